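analyte,wt_mean,wt_sd,wt_n,spfj_mean,spfj_sd,spfj_n,printed_p
Taurine,475.1,74.8,9,435.9,37.2,10,0.15
Aspartic Acid,20.1,3.2,9,19.3,3.1,10,0.58
Hydroxyproline,17.4,8.5,9,18,15.3,10,0.92
Threonine,219.6,19.7,9,185.4,13.5,10,<0.01
Serine,152.8,15.7,9,147.7,14.1,10,0.46
Asparagine,45.1,8.7,9,39.6,14,10,0.32
Glutamic Acid,40.2,12.3,9,36.9,7.7,10,0.48
Glutamine,654.7,67.1,9,768.3,28.2,10,<0.01
Proline,115.7,17.4,9,105.4,10.6,10,0.13
Glycine,302.1,63.7,9,253.2,55.3,10,0.09
Alanine,458.1,48.8,9,463.1,52.7,10,0.83
Citrulline,95.4,18.6,9,39.7,20.2,10,<0.01
Valine,251.6,19.5,9,216.6,19.1,10,<0.01
Methionine,87.7,7.9,9,78.9,11.7,10,0.08
Isoleucine,99.8,12.2,9,75.3,8.2,10,<0.01
Leucine,153.6,35.5,9,122.6,15.6,10,0.02
Tyrosine,116.2,12.5,9,106.8,13.7,10,0.14
Phenylalanine,74.4,6.7,9,68.8,8.7,10,0.14
Homocystine,0.6,0.9,9,0.1,0.3,10,0.14
Ornithine,95.3,14,9,73.4,8.3,10,<0.01
Lysine,386.4,39.5,9,331.1,41,10,<0.01
Histidine,75.4,8,9,79.7,8.8,10,0.29
Arginine,138.4,19.8,9,96.2,26.3,10,<0.01
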