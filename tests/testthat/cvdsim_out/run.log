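[2026-09-30 00:35:02] command=frobnicate config_hash=58e0494c51d30eb3494f7c9198986bb9 package=cvdmicrosim 0.1.0 R=R version 4.3.3 (2024-02-29) 
[2026-09-30 00:36:59] command=frobnicate config_hash=58e0494c51d30eb3494f7c9198986bb9 package=cvdmicrosim 0.1.0 R=R version 4.3.3 (2024-02-29) 
[2026-09-30 00:39:58] command=frobnicate config_hash=58e0494c51d30eb3494f7c9198986bb9 package=cvdmicrosim 0.1.0 R=R version 4.3.3 (2024-02-29) 
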