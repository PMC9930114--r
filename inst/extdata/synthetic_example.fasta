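>synthetic_320 synthetic random 320-residue test sequence (not a real protein)
SAKNIRQMVDDHWVFDFAEWEQCGFKSAFQEPVPETMKHNGVYQGENLQLWMDPPLWINI
PDTGNEYYCCDNSLSLGYTYEVWQPQIAIWTTQVWDDTWEPCPTKQLPCWHIWDSVWNKI
ILQYPEDIVHGIPHWVPIFMCVAHGEGPLSVQWREFWPMPNMFVKFDQMFQAYMIWWIWS
KFVYSWTIGAPMKEQFFIQCYHWGHKAYLYAGAPHPDARCMLHQGWYEYNCILLMFHERC
HLCYSQEYGEQIVSLLYCHINRVSKVMNIDVQPQQATDLEEYMHFHTYKPHTSDLNSHDC
IFALGSYKQQYQCFDLVTEW
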