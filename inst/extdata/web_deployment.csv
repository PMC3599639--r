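item,low_usd,high_usd
project_coordinator,17160,17160
server_hosting,150,450
advertising,510,5100
tech_support,10398,20796
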