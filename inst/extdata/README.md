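# Bundled fixtures

- `talpid_cytb329_synthetic_tree.nwk`, `talpid_cytb329_synthetic_states.tsv`:
  a SYNTHETIC stand-in for the talpid cytochrome-b phylogeny with the
  amino-acid state at protein position 329 at each tip. It encodes the
  published qualitative configuration (the two Galemys A-lineages share a
  derived residue; exactly two changes are parsimony-required, one of them
  on the branch subtending A1+A2) but is not the real species tree: taxa,
  topology and branch lengths beyond that configuration are invented.
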