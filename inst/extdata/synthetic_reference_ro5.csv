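id,swissadme,molinspiration
pep01,2,2
pep02,2,2
pep03,0,0
pep04,1,1
pep05,3,3
pep06,3,3
pep07,NaN,3
pep08,NaN,3
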