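analyte,wt_mean,wt_sd,wt_n,spfj_mean,spfj_sd,spfj_n,printed_p
Taurine,215,9.9,5,238.4,35.9,5,0.17
Aspartic Acid,245.2,31.9,5,294.7,52,5,0.11
Threonine,28.9,2,5,33.8,3.2,5,0.02
Serine,67,3.4,5,82.2,9.7,5,0.01
Asparagine,10,1,5,12.7,1.1,5,<0.01
Glutamic Acid,218.9,8.6,5,244.5,41.7,5,0.21
Glutamine,235,18.7,5,350.3,105.1,5,0.04
Proline,17,0.8,5,21.3,2.3,5,<0.01
Glycine,119.9,3.1,5,148.2,22.3,5,0.02
Alanine,87.2,12.2,5,104.6,24.8,5,0.19
Valine,13.4,1,5,16.5,1.9,5,0.01
Methionine,7.4,0.3,5,8.6,1,5,0.03
Isoleucine,8.5,0.6,5,10.2,1.2,5,0.02
Leucine,18.6,1,5,21.9,2.8,5,0.03
Tyrosine,8.7,0.6,5,12,2.6,5,0.03
Phenylalanine,9.7,0.3,5,11.8,1.8,5,0.03
Ornithine,1,0.2,5,1.3,0.2,5,0.03
Lysine,23.2,1.3,5,28.4,2.8,5,<0.01
Histidine,9.8,0.3,5,12.6,2.2,5,0.02
Arginine,23.4,0.7,5,24.8,3.6,5,0.41
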