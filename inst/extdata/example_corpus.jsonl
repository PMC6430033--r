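{"id":"m1","triplets":[["Rusty","eat","baguette"],["John","cook","scallop"],["Ole","bake","pizza"],["Boris","eat","chocolate"]],"pointers":[]}
{"id":"m2","triplets":[["John","cook","scallop"],["Natasha","drink","tea"]],"pointers":[]}
{"id":"m3","triplets":[["Marco","eat","bread"],["Natasha","see","movie"],["Boris","eat","chocolate"]],"pointers":[]}
{"id":"m4","triplets":[["Natasha","drink","beer"],["Ole","eat","cake"],["Rusty","eat","baguette"]],"pointers":[]}
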