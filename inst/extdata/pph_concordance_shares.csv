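basis,pph_quintile,q1,q2,q3,q4,q5
composite,1,7.3,6.2,3.5,2.0,1.1
composite,2,5.7,4.6,4.0,3.9,1.9
composite,3,2.3,2.6,5.1,5.2,5.1
composite,4,2.9,4.5,3.5,4.2,4.7
composite,5,1.6,2.2,3.9,4.9,7.3
socioeconomic,1,8.3,6.1,3.4,1.0,1.2
socioeconomic,2,4.6,5.8,4.3,3.4,2.1
socioeconomic,3,1.9,2.5,6.1,3.7,6.0
socioeconomic,4,3.3,3.5,3.0,5.5,4.6
socioeconomic,5,1.8,2.2,3.3,6.5,6.2
education,1,7.3,6.0,3.7,2.7,0.4
education,2,4.2,4.3,4.7,4.7,2.2
education,3,3.0,3.5,4.1,4.5,5.1
education,4,2.8,4.3,3.9,2.8,6.0
education,5,2.1,2.3,3.6,5.5,6.4
connectedness,1,7.2,5.5,3.0,2.5,1.8
connectedness,2,5.9,4.7,4.3,2.8,2.4
connectedness,3,2.1,4.4,5.2,3.9,4.6
connectedness,4,3.1,4.0,3.5,4.6,4.7
connectedness,5,1.7,1.3,4.2,6.2,6.6
housing,1,5.5,6.0,4.2,2.1,2.3
housing,2,6.8,4.0,3.9,3.6,1.8
housing,3,1.7,3.7,3.9,5.9,5.0
housing,4,3.5,4.2,4.4,4.2,3.5
housing,5,2.2,2.0,4.0,4.3,7.5
health_services,1,3.9,4.1,4.6,4.7,2.7
health_services,2,3.3,3.8,4.7,3.7,4.6
health_services,3,4.1,4.8,3.0,5.5,2.7
health_services,4,3.6,4.4,3.4,1.9,6.5
health_services,5,4.8,2.7,4.4,4.4,3.6
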