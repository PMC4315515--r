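analyte,wt_mean,wt_sd,wt_n,spfj_mean,spfj_sd,spfj_n,printed_p
Taurine,82.5,9.4,5,77.2,14.3,5,0.51
Aspartic Acid,94.5,11,5,63.2,12.4,5,<0.01
Threonine,41.5,1.8,5,34.3,7.5,5,0.07
Serine,59,3.3,5,49.2,10.3,5,0.07
Asparagine,26.8,2.9,5,22.2,3.7,5,0.06
Glutamic Acid,72.8,14.4,5,52.6,9.2,5,0.03
Glutamine,74.3,5.8,5,77.3,11,5,0.61
Proline,33,2.1,5,27.4,6.3,5,0.10
Glycine,84.2,5.8,5,74,9.9,5,0.08
Alanine,114.8,12,5,104.4,17,5,0.30
Valine,43.4,2,5,36.3,7.2,5,0.07
Methionine,18.8,1.2,5,15.6,3.1,5,0.07
Isoleucine,23.2,1.2,5,19.3,4.1,5,0.08
Leucine,44.3,2.4,5,38,6.4,5,0.07
Tyrosine,17.4,2.7,5,14,4.1,5,0.16
Phenylalanine,21.3,1.2,5,17.8,3.4,5,0.06
Ornithine,36.3,1.6,5,30,5.2,5,0.03
Lysine,51.2,2.6,5,45.2,7,5,0.11
Histidine,25.1,1.3,5,21.5,3.4,5,0.06
Arginine,0.8,0.3,5,0.6,0.3,5,0.25
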