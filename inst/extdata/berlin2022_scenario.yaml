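label: Berlin 2022 marathon
splits: berlin2022_splits.csv
roster: berlin2022_roster.csv
exposure: berlin2022_exposure.csv
catalog: default_catalog.csv
cooperative: yes
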