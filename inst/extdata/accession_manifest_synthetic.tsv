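# Synthetic placeholder manifest. Real screening studies deposit their
# allele sequences in a public archive; this package never fetches from
# the network, so users export FASTA from the fixtures instead and track
# their own accession ids here.
locus	allele	accession	note
EF1a	G	SYNTHETIC-0001	synthetic stand-in, not a database record
EF1a	H	SYNTHETIC-0002	synthetic stand-in, not a database record
COI	1	SYNTHETIC-0003	synthetic stand-in, not a database record
COI	2	SYNTHETIC-0004	synthetic stand-in, not a database record
CR	1	SYNTHETIC-0005	synthetic stand-in, not a database record
CR	2	SYNTHETIC-0006	synthetic stand-in, not a database record
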