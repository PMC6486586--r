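# Study conditions for the worked synthetic analysis: a national river
# network warming at 0.05 degC/yr while organic pollution (BOD) declines,
# with communities tracking the environment at rate 0.25 per year.
n_sites: 300
years: [1991, 2011]
n_taxa: 78
warming_slope: 0.05
bod_slope: -0.02
tracking_rate: 0.25
stress_weights: {temperature: 1.0, bod: 2.0}
sampling_prob: 0.8
detection_limit: 0.05
seed: 20260929
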