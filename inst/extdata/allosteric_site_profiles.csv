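position,helix,seq_part,x_part,gabab2,mglu1,mglu5,sift8,sift7
3.33x33,3,33,33,T557,R661,R648,0.67,0.74
3.36x36,3,36,36,L560,V664,I651,1,1
3.37x37,3,37,37,T561,G665,G652,0.7,0.67
3.40x40,3,40,40,Y564,S668,P655,1,1
3.41x41,3,41,41,T565,A669,A656,0.62,0.58
3.44x44,3,44,44,F568,Y672,Y659,0.71,0.79
5.39x39,5,39,39,W656,G752,G739,0.6,0.56
5.40x40,5,40,40,L657,V753,V740,0.9,1
5.43x43,5,43,43,V660,P756,P743,0.63,0.68
5.44x44,5,44,44,Y661,L757,L744,0.9,1
5.47x47,5,47,47,K664,N760,N747,0.99,1
5.48x48,5,48,48,G665,G761,G748,0.57,0.63
5.50x50,5,50,50,L667,L763,L750,0.46,0.52
5.51x51,5,51,51,M668,I764,I751,0.75,0.83
6.46x46,6,46,46,V699,T794,T781,0.9,1
6.49x49,6,49,49,M702,I797,I784,1,1
6.50x50,6,50,50,C703,W798,W785,1,1
6.53x53,6,53,53,G706,F801,F788,0.97,0.96
6.54x54,6,54,54,A707,V802,V789,0.9,0.88
6.57x57,6,57,57,S710,Y805,Y792,1,1
7.31x32,7,31,32,I723,T814,T801,0.68,0.75
7.32x33,7,32,33,V724,T815,M802,1,1
7.35x36,7,35,36,V727,A818,S805,0.9,1
7.36x37,7,36,37,I728,V819,V806,0.69,0.65
7.39x40,7,39,40,C731,S822,S809,0.98,1
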