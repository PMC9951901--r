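atom,x,y,z,mass
C1,1.397,0.0,0.0,12.011
C2,0.6985,1.2098591,0.0,12.011
C3,-0.6985,1.2098591,0.0,12.011
C4,-1.397,0.0,0.0,12.011
C5,-0.6985,-1.2098591,0.0,12.011
C6,0.6985,-1.2098591,0.0,12.011
C7,2.877,0.0,0.0,12.011
O0,-1.3805,-2.3911233,0.0,15.999
O1,3.502,1.0825318,0.0,15.999
O2,3.502,-1.0825318,0.0,15.999
O3,-1.3805,2.3911233,0.0,15.999
O4,-2.761,0.0,0.0,15.999
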