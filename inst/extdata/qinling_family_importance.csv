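belt,rank,taxon,r_ab,r_fr,ori
birch,1,Aceraceae,23.59,11.31,34.9
birch,2,Pinaceae,19.39,11.31,30.7
birch,3,Betulaceae,15.78,11.31,27.09
birch,4,Rosaceae,12.07,11.31,23.38
birch,5,Anacardiaceae,7.74,10.41,18.15
birch,6,Fagaceae,7.53,10.41,17.94
birch,7,Salicaceae,6.95,5.88,12.83
birch,8,Lauraceae,1.87,7.24,9.11
birch,9,Araliaceae,2.22,5.88,8.1
birch,10,Bignoniaceae,1.64,4.98,6.62
pine-oak,1,Pinaceae,46.84,17.24,64.08
pine-oak,2,Fagaceae,33.68,15.17,48.85
pine-oak,3,Anacardiaceae,6.8,13.79,20.59
pine-oak,4,Betulaceae,3.85,11.72,15.57
pine-oak,5,Lauraceae,2.18,8.97,11.15
pine-oak,6,Cornaceae,1.89,7.59,9.48
pine-oak,7,Juglandaceae,1.53,5.52,7.05
pine-oak,8,Aceraceae,1.13,5.52,6.65
pine-oak,9,Tiliaceae,0.69,3.45,4.14
pine-oak,10,Rosaceae,0.65,3.45,4.1
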