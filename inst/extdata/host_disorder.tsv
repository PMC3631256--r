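# Host proteome percent disorder (literature constants; mean/min/max over
# the proteomes of each host group). Joined into the host-level survey
# table; grouped host categories carry the mean of the groups they span.
host_category	host_mean	host_min	host_max
Bacteria	7.4	2.3	19.5
Fungi	21.5	9.0	32.5
Fungi/Protozoa	19.7	NA	NA
Invertebrates	17.6	11.2	23.7
Plants	20.1	11.5	28.9
Plants/Fungi	20.8	NA	NA
Vertebrates	21.1	17.6	30.3
Vert/Invert	19.6	NA	NA
Vert/Invert/Plants	19.6	NA	NA
Vert/Plants	20.6	NA	NA
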