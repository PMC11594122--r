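geoid,county,population,actual,predicted
29510124600,St. Louis,1845,46.00,37.63
29207470600,Stoddard,4968,39.80,48.32
29095005100,Jackson,1651,34.00,42.76
29095016100,Jackson,2046,49.80,40.42
29095008200,Jackson,2765,30.50,40.14
29510119300,St. Louis,5454,26.90,37.82
29095015400,Jackson,3826,52.80,41.61
29155470200,Pemiscot,3613,50.80,39.31
29095006100,Jackson,2542,48.30,61.83
29189213400,St. Louis,6669,37.40,52.07
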