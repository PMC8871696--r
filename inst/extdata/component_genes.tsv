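gene_id	gene_set
RNU11	component
RNU12	component
RNU4ATAC	component
RNU6ATAC	component
RNPC3	component
PDCD7	component
SNRNP48	component
SNRNP35	component
ZCRB1	component
SNRNP25	component
ZMAT5	component
ZRSR2	component
ZRSR1	component
ARMC7	component
TXNL4B	component
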