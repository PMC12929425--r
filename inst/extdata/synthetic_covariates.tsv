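network_id	latitude	longitude	bio4	bio10	bio15	bio18
synth001	43.9271732699126	54.672921281307936	684.8850247370806	18.010132613824634	37.17443862357038	56.663068898713824
synth002	63.20242004003376	-19.97860601171851	474.8502000495448	22.306353852718967	20.887012251144515	90.00808574236805
synth003	55.65683230292052	77.38484269939363	445.1292814556218	4.705635110927378	35.813686282902836	319.9273875908365
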