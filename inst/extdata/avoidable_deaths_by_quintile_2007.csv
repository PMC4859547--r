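basis,quintile,est_deaths,population_0_15
composite,1,240,747511
composite,2,175,759398
composite,3,189,752010
composite,4,163,756553
composite,5,114,757980
socioeconomic,1,229,750623
socioeconomic,2,191,757969
socioeconomic,3,167,752355
socioeconomic,4,164,756258
socioeconomic,5,130,756247
education,1,235,738789
education,2,164,766628
education,3,188,749371
education,4,153,762797
education,5,141,755866
connectedness,1,215,752973
connectedness,2,206,749644
connectedness,3,174,760712
connectedness,4,156,754042
connectedness,5,131,756081
housing,1,218,741278
housing,2,211,753022
housing,3,189,765405
housing,4,131,757058
housing,5,132,756688
health_services,1,195,751604
health_services,2,166,749686
health_services,3,159,755523
health_services,4,166,760827
health_services,5,195,755811
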