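# Example cohort configuration. Every field is optional; omitted fields
# fall back to the package defaults shown in ?cohort_config.
n_subjects: 206
p_sga: 0.063
p_lga: 0.136
p_term: 0.917
mean_visits: 4.76
noise_sd: 0.47
seed: 1
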