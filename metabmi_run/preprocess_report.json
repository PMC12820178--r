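{"discovery":{"n_input_metabolites":60,"n_excluded_missingness":0,"n_samples":148,"rf_iterations":5}}
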