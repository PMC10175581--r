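{"striatum":[[544.7,401.6],[479.2,429.7],[436.8,491.8],[420.3,490],[347.5,537],[328.2,509.2],[181,489.6],[140.3,422.6],[86.7,351.1],[378.3,106.1],[575.8,263.3],[574.5,283.8]]}
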