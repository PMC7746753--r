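# Synthetic example position frequency matrix (4 x 15, 100 sites per column).
# A GC-rich motif constructed for examples and tests; not derived from any
# experimental dataset.
A 10  5  8  6  4 10  5  6 10 70  8  6  5 12  9
C 15 75 70 14 80 68 10 12 66 10 12 70 15 64 72
G 65 12 12 72 10 14 75 74 12 15 70 14 72 12 11
T 10  8 10  8  6  8 10  8 12  5 10 10  8 12  8
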