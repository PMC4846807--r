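level,belt,rows,r_ab,r_fr,ori
family,birch,top10,98.78,90.04,188.82
family,birch,remainder,1.22,9.95,11.17
family,pine-oak,top10,99.24,92.42,191.66
family,pine-oak,remainder,0.76,7.59,8.35
genus,birch,top10,86.47,65.85,152.32
genus,birch,remainder,13.53,34.12,47.65
genus,pine-oak,top10,94.43,71.16,165.59
genus,pine-oak,remainder,5.56,28.77,34.33
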