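# Synthetic placeholder identifiers for the 27 universal single-copy KOs
# used to normalize KO profiles to per-genome-equivalent copy units.
# These ids are NOT real KEGG orthologs: the package does not ship the
# published USCG identity list, so real-data analyses must supply their
# own list (one ko_id per line) via the uscg argument/config field.
ko_id
uscg_K0001
uscg_K0002
uscg_K0003
uscg_K0004
uscg_K0005
uscg_K0006
uscg_K0007
uscg_K0008
uscg_K0009
uscg_K0010
uscg_K0011
uscg_K0012
uscg_K0013
uscg_K0014
uscg_K0015
uscg_K0016
uscg_K0017
uscg_K0018
uscg_K0019
uscg_K0020
uscg_K0021
uscg_K0022
uscg_K0023
uscg_K0024
uscg_K0025
uscg_K0026
uscg_K0027
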