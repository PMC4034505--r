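# raaindex

Reduce a database of amino-acid biochemical/physical property scales to a
minimal informative subset by random-forest permutation importance, and use
the resulting reduced index to encode protein sequences numerically and
characterize family diversity by PCA.

## Who this is for

Collections of amino-acid scales (hundreds of indices, each assigning one
measured value — hydropathy, polarity, contact number, … — to each of the
20 residues) are a natural bridge from protein sequences to numeric
features, but they are redundant and partly incomplete.  `raaindex` is for
sequence-analysis practitioners who want (a) a principled, reproducible
reduction of such a collection to a small subset of informative properties,
(b) a ready-made eight-property reduced table (rAAindex) for encoding, and
(c) a quantitative comparison of property encoding against the common
binary residue coding on their own aligned families.

## The method

With the 20 residues as statistical units, each property scale $x_i$ as an
explanatory variable and the binary hydropathy class $y$ of the residue as
response, the pipeline is:

1. drop properties with missing values;
2. backward-eliminate redundancy: remove properties until all pairwise
   Pearson $|r| \le 0.85$;
3. repeated random-forest trials scoring each property by permutation
   importance

   $$\mathrm{VIM}(x_i)=\frac{1}{ntree}\sum_{t=1}^{ntree}
     \bigl(\mathrm{err\,\widetilde{OOB}}_t-\mathrm{err\,OOB}_t\bigr),$$

   the mean over trees of the increase in out-of-bag misclassification
   counts when $x_i$'s out-of-bag values are permuted; properties with
   positive mean VIM are kept, ranked by decreasing mean;
4. nested forward selection: for growing prefixes of the ranking, refit
   forests and keep the longest prefix whose every step holds mean OOB
   error at or below 2%.

Sequences are then encoded as lattices: a gap-free homologous block of
length $L$ becomes an $L\times 8$ numeric matrix under the reduced table
(`bpp`), or an $L\times 8$ bit matrix under the ordinal binary code
(`binary8`).  Covariance PCA of the encoded sets quantifies how much
family diversity the leading components capture under each scheme.

## Worked example

```r
library(raaindex)

# the packaged eight-property reduced index
raaindex()
#> # A tibble: 20 × 9
#>    residue JACR890101 COWR900101 ZIMJ680103 MEEJ810102 ...
#>  1 A             0.18       0.42       0           1
#>  2 R            -5.4       -1.56      52          -2
#>  ...

# encoding a two-residue peptide: one row of 8 property values per residue
round(encode_bpp("AW"), 2)
#> pos1_JACR890101 pos1_COWR900101 pos1_ZIMJ680103 pos1_MEEJ810102 ...
#>            0.18            0.42            0.00            1.00 ...
#> pos2_JACR890101 ... pos2_MEEJ810102 ...
#>           -0.01 ...           15.10 ...

# synthetic four-family set (4 x 70 sequences, 28-residue block),
# property-structured divergence; compare the two encodings
aln <- gen_family_alignment(family_spec(seed = 42))
cmp <- compare_encodings(aln)
cmp
#> Encoding comparison: 280 sequences, 28 residue block
#> # A tibble: 2 × 4
#>   scheme  pc1_pct pc2_pct pc12_pct
#> 1 bpp        46.1    32.8     78.9
#> 2 binary8    24.2    20.0     44.2
```

The last table is the package's headline comparison: on families whose
divergence is structured in property space, the first two principal
components of the property-encoded set explain 78.9% of the variance
against 44.2% for the binary baseline — the property code concentrates
family structure into far fewer dimensions.  `autoplot(cmp)` draws the
side-by-side score scatter; `tidy()`/`glance()` methods return all results
as tibbles.

Running the reduction itself on your own scale collection:

```r
props <- read_aaindex("scales.aaindex")           # flat-file dialect
red   <- reduce_pipeline(props, config = rf_config(seed = 1))
tidy(red)          # per-stage retained/dropped counts
red$selected       # the chosen accessions
autoplot(red$selection)   # nested error curve against the 2% bar
```

A command-line interface with the same functionality (subcommands
`reduce`, `encode`, `pca`, `compare`, `simulate`) is installed as
`exec/raaindex`; every output carries a provenance JSON sidecar.

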