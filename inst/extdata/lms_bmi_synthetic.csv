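sex,agemos,L,M,S
female,60,-1.2,15.2,0.085
female,84,-1.6,15.8,0.100
female,108,-2.0,16.9,0.115
female,132,-2.2,18.4,0.125
female,156,-2.1,19.9,0.130
female,180,-1.9,21.0,0.130
female,204,-1.7,21.7,0.125
male,60,-1.6,15.4,0.080
male,84,-2.2,15.9,0.100
male,108,-2.6,16.8,0.120
male,132,-2.6,18.0,0.130
male,156,-2.3,19.5,0.135
male,180,-2.0,20.9,0.130
male,204,-1.8,22.0,0.120
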