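/* 47 individuals, 8 primary periods x (6,6,6,6,6,6,6,6) secondary occasions */
000000000101000000000000000000000000000000000000 1;
000000000000000000000000000000000001000000000000 1;
000110001001000000000000000000000000000000000000 1;
000000000000001000000000000000000000000000000000 1;
000000000001000000001010000000000000000000101000 1;
000000000000000000111000000000000000000000000000 1;
000001000000000000000000000000000000000000000000 1;
000100000000000000000000000000000000000000000000 1;
000000000000000000000000000000000000000100000001 1;
000000000000000000001000000000000000001000010000 1;
000000000000000100000001001100000000000000000000 1;
000000000000000010000000000000000000000000000000 1;
100000010000110000001000000100000100000000011110 1;
000000010000000000000000000000000001000000000000 1;
000000001000000000000000010000000000000100010000 1;
000000000000000011100000100000010000000000000000 1;
000000000100000000000000000000000000000000000000 1;
000000000000100000000010000000000000000010000000 1;
000001000000000000000000000000000000000000000000 1;
000000000000001000000000000000000000000000000000 1;
000000000000000000000000000000010000010000001010 1;
000000000000000101000000000000000000000000000000 1;
011000000000000100000000000000000110010000000000 1;
000000000000000000000000000000000000000000000010 1;
000100000000000000000000000000000000000000000000 1;
000000001010000000000000010010000010000001000000 1;
101000000000010000100000000000100000000000000000 1;
000000000000010000000010000000000000000000000000 1;
000000000000010010000000000000000001000101001000 1;
000000000000001000000000000000000100001100000000 1;
000000000000000000000000100000000000000000000000 1;
000000000000000001000001111000000000000000000001 1;
000000010000000000000000000000000000000000000000 1;
100000101101000100000000000010110000000000000000 1;
000001000100000000000000000000000000000000000000 1;
000000100100000000000000000000000001000000001100 1;
100000011000000000000000000000000000000000110000 1;
001110000000000000000000000000000000000000000000 1;
000000000000000000000000000110001101000100000001 1;
100000000100000000000000000000000000000000000000 1;
000000000001011000000010000010010000000000000000 1;
000000001000000000010000000000000000000000000000 1;
001101000000000000000000000000000000000100000000 1;
000000000000000000000101000000000001000000000000 1;
000000010000000000000000000110000000010110000000 1;
000110000000000000000000000000000000000000000000 1;
000000000000000000000001011100000001100000000000 1;
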