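model,class,total,correct
overlock_s,botrytis,392,386
overlock_s,rust,375,371
overlock_s,blight,325,312
overlock_s,purple,358,346
overlock_s,healthy,369,368
efficientformer,botrytis,392,384
efficientformer,rust,375,369
efficientformer,blight,325,311
efficientformer,purple,358,345
efficientformer,healthy,369,368
mobilemamba,botrytis,392,386
mobilemamba,rust,375,371
mobilemamba,blight,325,314
mobilemamba,purple,358,349
mobilemamba,healthy,369,366
proposed,botrytis,392,390
proposed,rust,375,373
proposed,blight,325,318
proposed,purple,358,350
proposed,healthy,369,368
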