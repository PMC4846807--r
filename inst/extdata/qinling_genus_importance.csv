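belt,rank,taxon,r_ab,r_fr,ori
birch,1,Acer,23.59,7.55,31.14
birch,2,Betula,10.02,7.55,17.57
birch,3,Pinus,8.52,7.55,16.07
birch,4,Sorbus,8.45,7.55,16
birch,5,Toxicodendron,7.74,6.95,14.69
birch,6,Tsuga,7.6,6.95,14.55
birch,7,Quercus,7.53,6.95,14.48
birch,8,Carpinus,3.99,6.34,10.33
birch,9,Cerasus,3.61,5.74,9.35
birch,10,Populus,5.42,2.72,8.14
pine-oak,1,Pinus,44.33,14.12,58.45
pine-oak,2,Quercus,33.68,12.43,46.11
pine-oak,3,Toxicodendron,6.58,11.3,17.88
pine-oak,4,Carpinus,2.58,7.34,9.92
pine-oak,5,Lindera,1.85,6.21,8.06
pine-oak,6,Juglans,1.27,4.52,5.79
pine-oak,7,Acer,1.13,4.52,5.65
pine-oak,8,Tsuga,1.09,3.95,5.04
pine-oak,9,Betula,0.76,3.95,4.71
pine-oak,10,Larix,1.16,2.82,3.98
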