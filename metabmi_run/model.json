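{"training_column_ids":["M0001","M0002","M0003","M0004","M0005","M0006","M0007","M0008","M0009","M0010","M0011","M0012","M0013","M0014","M0015","M0016","M0017","M0018","M0019","M0020","M0021","M0022","M0023","M0024","M0025","M0026","M0027","M0028","M0029","M0030","M0031","M0032","M0033","M0034","M0035","M0036","M0037","M0038","M0039","M0040","M0041","M0042","M0043","M0044","M0045","M0046","M0047","M0048","M0049","M0050","M0051","M0052","M0053","M0054","M0055","M0056","M0057","M0058","M0059","M0060"],"weights":{"M0001":0,"M0002":-0,"M0003":-0,"M0004":-0,"M0005":-0,"M0006":-0,"M0007":0,"M0008":-0.355744274443603,"M0009":0,"M0010":-0,"M0011":-0,"M0012":-0.03375755950417,"M0013":0,"M0014":-0,"M0015":0,"M0016":0,"M0017":-0,"M0018":0,"M0019":0,"M0020":0,"M0021":0,"M0022":0.169461606959472,"M0023":-0.098700724134655,"M0024":0,"M0025":0,"M0026":-0,"M0027":0,"M0028":0,"M0029":0,"M0030":0,"M0031":-0.283013617900575,"M0032":0,"M0033":-0,"M0034":0,"M0035":-0,"M0036":0.395120661150533,"M0037":-0,"M0038":0.16449783561352,"M0039":-0,"M0040":0,"M0041":-0,"M0042":0.312665317735957,"M0043":-0.321726038633368,"M0044":0,"M0045":-0,"M0046":0,"M0047":-0.331971674785544,"M0048":-0,"M0049":0,"M0050":0,"M0051":0.225039932318778,"M0052":0,"M0053":-0.452891338803731,"M0054":-0,"M0055":0,"M0056":0.0534276481338187,"M0057":-0,"M0058":0,"M0059":-0.0221427029974469,"M0060":-0},"eta":0.3,"intercept":-6.30256539455808e-17,"slope":0.31083029400508,"rmsecv":0.826575879747106,"r2cv":0.313947616450128,"r2_insample":0.364730331060073,"training_standardisation":[{"id":"M0001","mean":2.9505754533995,"sd":0.996144892781986},{"id":"M0002","mean":3.25719449211071,"sd":0.990511626365533},{"id":"M0003","mean":6.9854289164242,"sd":1.08974488953094},{"id":"M0004","mean":6.45209773230414,"sd":0.958007781620765},{"id":"M0005","mean":3.30184861994669,"sd":1.05509940672178},{"id":"M0006","mean":5.41139922543831,"sd":0.943511204280742},{"id":"M0007","mean":6.66568592028348,"sd":0.98907028243493},{"id":"M0008","mean":6.15500936454463,"sd":1.08099008470988},{"id":"M0009","mean":5.18173574014781,"sd":1.05058339063967},{"id":"M0010","mean":7.46492908842589,"sd":0.919916411143801},{"id":"M0011","mean":6.80100360479699,"sd":1.1310603280196},{"id":"M0012","mean":4.06632772998567,"sd":1.0375632765282},{"id":"M0013","mean":7.43838414643962,"sd":0.965919679273379},{"id":"M0014","mean":5.11467425829323,"sd":0.983636066356347},{"id":"M0015","mean":7.63110933033269,"sd":1.01499690439709},{"id":"M0016","mean":3.34933774739175,"sd":1.04055680236233},{"id":"M0017","mean":4.86216537497348,"sd":0.924548498765944},{"id":"M0018","mean":5.15787708414343,"sd":0.967837271302894},{"id":"M0019","mean":7.58961645124312,"sd":1.02385058409839},{"id":"M0020","mean":4.752449620267,"sd":0.996849270832592},{"id":"M0021","mean":3.33668737799767,"sd":0.915285706127191},{"id":"M0022","mean":4.90328896218495,"sd":0.978886917877209},{"id":"M0023","mean":3.46854577857486,"sd":1.11331546377236},{"id":"M0024","mean":3.67129087143496,"sd":0.910216518592749},{"id":"M0025","mean":7.75568434995386,"sd":0.944057415726721},{"id":"M0026","mean":3.00984311526954,"sd":0.903734551731051},{"id":"M0027","mean":7.62070872985753,"sd":1.02393408741044},{"id":"M0028","mean":7.57216079399136,"sd":1.07360162302486},{"id":"M0029","mean":5.85993771180726,"sd":0.881720876730421},{"id":"M0030","mean":6.07077725744498,"sd":0.886425055868314},{"id":"M0031","mean":6.7596462204543,"sd":1.21128144861911},{"id":"M0032","mean":5.6735279282173,"sd":0.914929259243214},{"id":"M0033","mean":5.70354064284785,"sd":1.00567831801007},{"id":"M0034","mean":7.01150036232623,"sd":1.04111530774547},{"id":"M0035","mean":7.63903165218003,"sd":1.01345388928757},{"id":"M0036","mean":6.52500626068165,"sd":1.42064008348225},{"id":"M0037","mean":6.89230895404141,"sd":0.951947762159024},{"id":"M0038","mean":7.94869996995121,"sd":0.918777953295126},{"id":"M0039","mean":3.62928418169483,"sd":1.01993618799597},{"id":"M0040","mean":5.88847649858426,"sd":0.959145617153553},{"id":"M0041","mean":3.4142136421919,"sd":1.03005764495008},{"id":"M0042","mean":7.62331316661928,"sd":1.05101003121057},{"id":"M0043","mean":7.80535847888667,"sd":1.19574982221044},{"id":"M0044","mean":7.24314606325184,"sd":0.917338654791635},{"id":"M0045","mean":4.78389999904869,"sd":0.96719567636493},{"id":"M0046","mean":4.13175173758242,"sd":0.992522954014905},{"id":"M0047","mean":4.07766737232148,"sd":1.34616822600382},{"id":"M0048","mean":5.79545879991836,"sd":1.05800758964905},{"id":"M0049","mean":5.40950453466382,"sd":0.993077028984976},{"id":"M0050","mean":3.64348636912558,"sd":1.04715198876985},{"id":"M0051","mean":6.96808086735864,"sd":1.23604261667166},{"id":"M0052","mean":4.53759133004581,"sd":0.851096417577905},{"id":"M0053","mean":4.52790640039249,"sd":1.34680521170751},{"id":"M0054","mean":3.64812227364074,"sd":0.85543246141673},{"id":"M0055","mean":3.99100966524458,"sd":0.984726270082943},{"id":"M0056","mean":4.02590017550737,"sd":1.06825888346501},{"id":"M0057","mean":5.54929559154353,"sd":0.844595696944504},{"id":"M0058","mean":6.75630490569565,"sd":0.953109855237316},{"id":"M0059","mean":4.81033531068079,"sd":0.956413499623787},{"id":"M0060","mean":4.58917164464621,"sd":0.905013070642624}],"response_center_scale":{"mean":24.0577456301297,"sd":4.28026167641477}}
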