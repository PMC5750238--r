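# Flagship high-FRET construct: flipped Spinach (S*) and Mango each 5 bp
# from the reference crossover on sister helices, internal 180-degree
# kissing loop between the crossovers, UUCG tetraloops at the far ends.
NAME S*5-M5
HELIX 1 35
HELIX 2 35
XOVER 1 6 2 6
XOVER 1 27 2 27
MOTIF SPINACH 1 1 flipped
MOTIF MANGO 2 1 normal
MOTIF KL180 1 16 normal
MOTIF TETRALOOP_UUCG 1 35 normal
MOTIF TETRALOOP_UUCG 2 35 normal
END5 2 20 bottom
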