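{"seed":5,"stages":{"simulate":{"status":"completed","summary":{"n_discovery":150,"n_metabolites":60,"missing_frac_discovery":0.0474,"n_validation":150}},"preprocess":{"status":"completed","summary":{"n_retained_discovery":60,"n_excluded_discovery":0,"n_samples_discovery":148,"n_retained_validation":60,"n_samples_validation":148}},"score":{"status":"completed","summary":{"selected_eta":0.3,"n_selected":14,"n_overlap":60,"rmsecv":0.826576,"r2cv":0.313948}},"associate":{"status":"skipped"},"enrich":{"status":"skipped"},"mediate":{"status":"skipped"}},"timing_s":{"simulate":0.063,"preprocess":13.005,"score":0.062}}
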