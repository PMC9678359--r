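cohort,stimulus,rating1,rating2,rating3,rating4
patient,Hand,0.1357,0.2643,0.3690,0.2310
patient,Face,0.3976,0.3262,0.2000,0.0762
control,Hand,0.3301,0.3889,0.2125,0.0685
control,Face,0.4455,0.3276,0.1699,0.0570
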