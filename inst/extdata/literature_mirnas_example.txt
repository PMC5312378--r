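hsa-miR-16-5p
hsa-miR-17-5p
hsa-miR-20a-5p
hsa-miR-20b-5p
hsa-miR-21-3p
hsa-miR-25-3p
hsa-miR-29a-3p
hsa-miR-29c-3p
hsa-miR-30c-5p
hsa-miR-31-5p
hsa-miR-34a-5p
hsa-miR-92a-3p
hsa-miR-101-3p
hsa-miR-145-3p
hsa-miR-145-5p
hsa-miR-148a-3p
hsa-miR-151a-3p
hsa-miR-215
hsa-miR-221-3p
hsa-miR-224-5p
hsa-miR-335-5p
hsa-miR-370
hsa-miR-374a-5p
hsa-miR-425-5p
hsa-miR-490-5p
hsa-miR-500a-5p
hsa-miR-570-3p
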