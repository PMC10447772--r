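state,year,deaths,population,gun_ownership,violent_crime_rate,property_crime_rate
AA,1999,120,4000000,35.2,410.5,3100.2
AA,2000,131,4010000,34.8,398.7,3050.9
BB,1999,45,1500000,55.1,300.2,2800.4
BB,2000,52,1510000,54.6,310.8,2850.1
CC,1999,210,6200000,28.4,520.9,3400.7
CC,2000,198,6230000,29.1,505.3,3380.2
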