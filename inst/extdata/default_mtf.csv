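"frequency_cycles_per_mm","modulation"
0,1
0.0246305418719212,0.996444229437296
0.0492610837438424,0.985852599105208
0.0738916256157636,0.968449474739319
0.0985221674876847,0.944600003843048
0.123152709359606,0.914797377560558
0.147783251231527,0.879645877644992
0.172413793103448,0.839840522197871
0.197044334975369,0.796144266843363
0.221674876847291,0.749363803372938
0.246305418719212,0.700325022339459
0.270935960591133,0.649849170614001
0.295566502463054,0.598730644636489
0.320197044334975,0.547717223578603
0.344827586206897,0.497493375135306
0.369458128078818,0.448667073060731
0.394088669950739,0.401760363330199
0.41871921182266,0.357203717938693
0.443349753694581,0.315334033437753
0.467980295566503,0.276395974839621
0.492610837438424,0.24054624132608
0.517241379310345,0.207860242273422
0.541871921182266,0.178340621580551
0.566502463054187,0.151927053692657
0.591133004926108,0.12850675238805
0.61576354679803,0.107925178031532
0.640394088669951,0.0899964942369325
0.665024630541872,0.074513403919889
0.689655172413793,0.0612560808603585
0.714285714285714,0.05
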