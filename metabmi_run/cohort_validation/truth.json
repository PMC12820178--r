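{"signal_ids":["M0008","M0022","M0028","M0031","M0036","M0042","M0043","M0047","M0051","M0053"],"mediator_ids":["M0028","M0031","M0053"],"true_weights":{"M0008":-0.603190608276054,"M0022":0.452351105771959,"M0028":0.429445581696928,"M0031":-0.836126138502732,"M0036":0.87996048242785,"M0042":0.447212173510343,"M0043":-0.68626478468068,"M0047":-0.925356339011341,"M0051":0.799467392964289,"M0053":-0.702679344220087},"true_outcome_coefs":{"gestational_diabetes":{"name":"gestational_diabetes","intercept":-3.05504885071041,"bmi_logor":0.2,"mediator_logors":{"M0028":0.3,"M0031":-0.3,"M0053":-0.3}},"preeclampsia":{"name":"preeclampsia","intercept":-3.17805383034795,"bmi_logor":0.15,"mediator_logors":{"M0028":0,"M0031":-0,"M0053":-0}},"cesarean_section":{"name":"cesarean_section","intercept":-1.3249254147436,"bmi_logor":0.2,"mediator_logors":{"M0028":0,"M0031":-0,"M0053":-0}}},"pathway_assignment":{"M0001":"SP21","M0002":"SP02","M0003":"SP16","M0004":"SP16","M0005":"SP09","M0006":"SP20","M0007":"SP06","M0008":"SP01","M0009":"SP18","M0010":"SP01","M0011":"SP12","M0012":"SP15","M0013":"SP01","M0014":"SP08","M0015":"SP08","M0016":"SP08","M0017":"SP21","M0018":"SP03","M0019":"SP02","M0020":"SP21","M0021":"SP02","M0022":"SP04","M0023":"SP13","M0024":"SP09","M0025":"SP09","M0026":"SP17","M0027":"SP23","M0028":"SP15","M0029":"SP10","M0030":"SP12","M0031":"SP04","M0032":"SP18","M0033":"SP09","M0034":"SP22","M0035":"SP08","M0036":"SP15","M0037":"SP22","M0038":"SP03","M0039":"SP12","M0040":"SP22","M0041":"SP03","M0042":"SP02","M0043":"SP04","M0044":"SP16","M0045":"SP10","M0046":"SP07","M0047":"SP06","M0048":"SP24","M0049":"SP23","M0050":"SP12","M0051":"SP16","M0052":"SP17","M0053":"SP02","M0054":"SP16","M0055":"SP16","M0056":"SP11","M0057":"SP09","M0058":"SP19","M0059":"SP21","M0060":"SP13"}}
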