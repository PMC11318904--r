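site,elevation,nri,nti,ses_pd,plant_richness_z,predator_abundance_z,temperature_z
Kausi,200,0.21,2.51,-2.22,-0.22,1.51,1.48
Bobvrai,700,-0.08,1.21,-0.88,1.11,1.19,1.08
Koviamarai,1200,-0.31,-0.35,0.69,1.26,0.53,0.56
Bananumbu,1700,2.81,1.32,-1.35,0.54,-0.11,0.36
Sinopass,2200,3.05,2.11,-2.59,-0.84,-0.43,-0.14
Kiagimanigi,2700,1.66,4.60,-5.43,0.29,-0.05,-0.59
Kombugo Manuno,3200,0.10,4.61,-4.43,-0.12,-0.87,-1.19
Piunde Lake,3700,2.63,2.18,-3.11,-2.01,-1.76,-1.55
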