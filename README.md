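# nsltp

Identification and classification of plant **non-specific lipid transfer
proteins (nsLTPs)** from their eight-cysteine scaffold.

nsLTPs are small, mostly basic plant proteins stabilised by four
disulfide bonds between eight conserved cysteines.  The cysteines span
the consensus motif

```
C-Xn-C-Xn-CC-Xn-CXC-Xn-C-Xn-C        (the "8-Cys motif")
```

where `Xn` is a variable-length spacer.  Two features of this scaffold
carry nearly all of the family's classification signal:

* **inter-cysteine spacing** — the number of residues in the five
  variable gaps (g1: Cys1–Cys2, g2: Cys2–Cys3, g3: Cys4–Cys5,
  g4: Cys6–Cys7, g5: Cys7–Cys8) separates nsLTPs into five types
  (I–V), refining the older nsLTP1 (~9 kDa) / nsLTP2 (~7 kDa) split;
* **the CXC X residue** — hydrophilic (e.g. asparagine) in nsLTP1-like
  proteins, hydrophobic (e.g. leucine, phenylalanine) in nsLTP2-like
  ones.

The package implements the full identification/classification pipeline
as composable R functions:

| area | functions |
|---|---|
| IO | `read_fasta()`, `write_fasta()`, `read_alignment()`, `dedupe_identical()` |
| motif | `find_cys_motifs()`, `find_deficient_motifs()`, `motif_report()` |
| classification | `classify_spacing()`, `classify_sequence()`, `classify_set()`, `spacing_rules()` |
| Prosite patterns | `parse_pattern()`, `render_pattern()`, `scan_pattern()`, `builtin_patterns()` |
| pattern induction | `column_profiles()`, `induce_pattern()` |
| physicochemistry | `molecular_weight()`, `net_charge()`, `isoelectric_point()`, `cxc_polarity()` |
| phylogenetics | `pairwise_identity()`, `distance_matrix()`, `upgma()`, `neighbor_joining()`, `write_newick()` |
| simulation | `sample_from_pattern()`, `sample_type_sequences()`, `make_decoys()`, `synthetic_alignment()` |
| CLI | `ltp_cli()` and the `exec/nsltp` script |

The Prosite engine ships the published Type I and Type II nsLTP
patterns and the classic PLANT_LTP entry PS00597 as built-ins, and
`induce_pattern()` reproduces the pattern-definition strategy: compute
the occurrence of the 20 amino acids at every alignment column, emit a
literal where one residue dominates, a residue class where a few do,
and a bounded wildcard `x(m,M)` elsewhere.

## Worked example

```r
library(nsltp)

# simulate two Type I and two Type II nsLTP-like sequences
seqs <- rbind(sample_type_sequences("I",  2, seed = 7),
              sample_type_sequences("II", 2, seed = 8))

classify_set(seqs, use_patterns = TRUE)[, c("sequence_id", "resolved",
  "g1", "g2", "g3", "g4", "g5", "cxc_x", "cxc_polarity", "mw_da", "pi")]
#>   sequence_id resolved g1 g2 g3 g4 g5 cxc_x cxc_polarity mw_da    pi
#> 1  typeI_sim1        I 10 15 20 20 14     Q  hydrophilic 16246 9.060
#> 2  typeI_sim2        I 10 13 18 19 13     D  hydrophilic 15571 5.952
#> 3 typeII_sim1       II  7 13  9 24  7     A  hydrophobic 10858 6.022
#> 4 typeII_sim2       II  7 15 10 21  6     W  hydrophobic  9417 6.424
```

Each row reports the resolved type, the five inter-cysteine gap counts
that drove the call, the CXC X residue and its polarity class, and the
computed molecular weight (Da) and isoelectric point.  The underlying
motif coordinates are available directly:

```r
find_cys_motifs(seqs$seq[1])
#>   c1 c2 c3 c4 c5 c6 c7 c8 g1 g2 g3 g4 g5 n_offset c_tail cxc_x
#> 1 10 21 37 38 59 61 82 97 10 15 20 20 14        9     37     Q
```

Scanning with a Prosite pattern enumerates every match span:

```r
scan_pattern("LPAACALAVAFAISAAADCAAL", builtin_patterns()$PS00597)
#>   start end
#> 1     1  22
```

And the same sequence set feeds the distance/tree stage:

```r
cat(write_newick(upgma(distance_matrix(seqs))))
#> ((typeI_sim1:0.427268,(typeII_sim1:0.395000,typeII_sim2:0.395000):0.032268):0.011408,typeI_sim2:0.438676):0.000000;
```

The same pipeline is available from a shell via the installed script:

```sh
nsltp simulate --type II --n 20 --seed 1 --out seqs.fasta
nsltp classify seqs.fasta --use-patterns --out report.tsv
nsltp tree seqs.fasta --method nj --out tree.nwk
```

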