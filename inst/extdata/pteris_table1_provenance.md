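# Provenance notes for `pteris_table1.tsv`

The packaged genotype table transcribes the published sample/genotype table of
the *Pteris fauriei* group (72 rows, one representative sample per genotype
entry). The published layout uses ditto marks ("=", same as the field above)
and "–" (no data); this file ships fully expanded: dittos are resolved and
"–" becomes an empty cell. Multiplication signs in hybrid formulas are written
as a plain `x`; typographic primes in haplotype labels are normalised to an
ASCII apostrophe (`cf'`, `ca'`); primed labels are distinct haplotypes.
Elevation "h to l" is coded `both`. Ploidy "2x"/"2X" is coded `2`, "3X" is
`3`.

Row-level judgment calls (the source table's columns are run together in the
available text, so a few boundaries required interpretation):

- Rows 6-8 (*P. arisanensis*, D5F3 / D7F3G1): the hybrid-formula cell is "–"
  in the source even though the rows sit under the "P. latipinna x
  P. arisanensis" block; the formula is left empty rather than propagated.
  Likewise rows 30-31, 35-36 and 61 carry no formula of their own.
- Row 10 (*P. biaurita*, S25S25): the nuclear *Knox3* cell is "–" (no data)
  and no reproductive-mode token is printed; both are empty here.
- Row 18 (Yang191029002): all of formula, *Knox3* and *IBR3* are dittos of
  row 17 (F16G1 / S14Y87); ploidy is "–". The printed maternal lineage (G1,
  S14) differs from row 17 (F16, Y87) and is kept verbatim.
- Row 24 (*P.* aff. *confusa* F1F1): the haplotype cell is garbled in the
  available text; the results section assigns haplotype `cu` to this taxon,
  which is used here. Row 25 (F1F2) prints "–" for both *IBR3* and cpDNA;
  both are empty.
- Row 31 (Chao2805): genotype printed "A11D32*", maternal lineage printed
  "A?"; both kept verbatim (D32 is a valid allele label in the source's
  scheme).
- Row 49 (Chao2182): maternal lineage printed "H1 = H6"; transcribed as `H1`.
- Row 19: haplotype printed "ca’" with ploidy "2x"; coded `ca'`, ploidy 2.
- Row 35: sample printed "Wade3659–1" (en dash); coded `Wade3659-1`.
- Reproductive modes are transcribed as printed (`sex`/`apo`); per-sample
  spore counts are not printed in the source table (sexual plants have 64
  spores per sporangium, apogamous plants 32 or fewer).
- Habitat is not a column of the source table; the loader attaches a
  taxon-level habitat (open for *P. minor*, semi-shade for *P. fauriei*,
  shade for *P. latipinna*, unknown otherwise) from statements in the source
  text.
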