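value,unit,ruler_name
4.81,um,conoid
5.45,um,conoid
5.7,um,conoid
5.09,um,conoid
4.77,um,conoid
5.27,um,conoid
5.49,um,conoid
5.74,um,conoid
4.81,um,conoid
4.78,um,conoid
5.58,um,conoid
5.49,um,conoid
5.91,um,conoid
5.69,um,conoid
5.26,um,conoid
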