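# Nine benchmark spaced seeds, weight 22, span 31.
# Q1-Q3: maximal hit probability; Q4-Q6: minimal overlap complexity;
# Q7-Q9: maximal sensitivity.
1111011101110010111001011011111  # Q1
1111101011100101101110011011111  # Q2
1111101001110101101100111011111  # Q3
1111010111010011001110111110111  # Q4
1110111011101111010010110011111  # Q5
1111101001011100111110101101111  # Q6
1111011110011010111110101011011  # Q7
1110101011101100110100111111111  # Q8
1111110101101011100111011001111  # Q9
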