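subnetwork	beta
subnetwork_1	-1.4
subnetwork_2	-1.1
subnetwork_3	-1.3
subnetwork_4	-1.4
subnetwork_5	-1.0
subnetwork_6	1.2
subnetwork_7	1.0
subnetwork_8	-1.2
subnetwork_9	1.1
subnetwork_10	1.0
subnetwork_11	-1.2
subnetwork_12	1.0
subnetwork_13	-1.2
subnetwork_14	1.0
subnetwork_15	-1.9
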