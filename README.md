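# carna — landscape analysis of RNA–chromatin interactions

Proximity-ligation assays of the iMARGI/GRID-seq family capture
chromatin-associated RNAs (caRNAs) as read pairs with one RNA end and one
DNA end. `carna` takes such contact pairs from the point where upstream
processing ends (valid, deduplicated pairs aligned to a reference) and
answers the questions a landscape study asks of them:

- **Which RNA produced each contact, and what class of RNA is it?**
  Each RNA end is assigned to its source gene by same-strand interval
  overlap, with a configurable class priority (small ncRNA ≻ lncRNA ≻
  protein-coding) so that a snoRNA nested inside a host gene is credited
  to the snoRNA, not the host.
- **Is the contact cis or trans?** A contact is *cis* when both ends map
  to the same chromosome (at any distance) and *trans* otherwise.
- **What does the class-level landscape look like?** Per class:
  cis/trans counts, share of all cis and of all trans contacts, and the
  trans fraction within the class.
- **Which RNAs act in trans?** A gene is called trans-acting when
  `n_total >= 10` contacts and `n_trans / n_total >= 0.20` (both
  thresholds inclusive and configurable); called genes are ranked by
  trans-contact count.
- **Where does a given RNA touch the genome?** Per-RNA genome-wide
  interaction maps: binned DNA-end frequencies plus a cis/trans-labelled
  arc table for circos-style plotting.
- **What chromatin states do contact regions fall into?** A
  regions × marks matrix of mean CPM signal, k-means clustering into
  activity groups C1..Ck (C1 = highest H3K27ac by default), average
  signal profiles, and between-condition log2-ratio comparisons.

A truth-known synthetic-data generator (genome, nested annotation,
contact pairs with per-class trans rates and exponential cis-distance
decay, mark tracks with planted clusters) makes every stage testable
without sequencing data.

## Worked example

Simulate a small study with known truth and run the analysis:

```r
library(carna)

asm   <- make_genome(n_chroms = 4, lengths = 2e6)
genes <- make_annotation(asm,
  c(protein_coding = 20, lncRNA = 10, snoRNA = 8, snRNA = 4),
  nest_snorna_in_hosts = 0.5, seed = 2)
sim      <- simulate_contacts(genes, asm, contact_sim_config(50000, seed = 3))
contacts <- annotate_contacts(sim$pairs, genes)

class_landscape(contacts)
#> RNA-chromatin interaction landscape
#>   50000 contacts: 45242 cis, 4758 trans (global cis fraction 0.905)
#>   0 unannotated contacts excluded from class shares
#>       rna_class n_cis n_trans share_of_cis share_of_trans trans_fraction_within_class
#>  protein_coding 37132     842      0.82074         0.1770    0.0222
#>          lncRNA  7171     198      0.15850         0.0416    0.0269
#>          snoRNA   667    2468      0.01474         0.5187    0.7872
#>           snRNA   272    1250      0.00601         0.2627    0.8213
#>           ...

call_trans_acting(gene_profiles(contacts))
#> trans-acting RNAs: 12 called (>= 10 contacts, >= 20% trans)
#>       gene_id rna_class n_total n_trans trans_fraction
#> 1  snoRNA_006    snoRNA     414     337      0.8140097
#> 2   snRNA_002     snRNA     403     333      0.8263027
#> ...
```

Reading the output: protein-coding mRNAs dominate the cis landscape
(82% of cis contacts) but contact chromatin almost exclusively near
their own locus (trans fraction 0.02), while snoRNAs and snRNAs —
simulated with a 0.8 trans rate — account for most trans contacts and
are the genes the dual-threshold caller flags. A per-RNA map exports the
genome-wide picture for one gene:

```r
m <- interaction_map("snoRNA_006", contacts, genes, asm, bin_size = 5e5)
m
#> interaction_map for snoRNA_006 (snoRNA): 414 contacts in 13 bins (bin 500000 bp)
write_interaction_map(m, "snoRNA_006_arcs.tsv")
```

File-based runs go through `run_full()` (or
`inst/scripts/carna-run.R --config run.yaml`), which reads the pairs
dialect, GTF, chrom.sizes, BED and bedGraph inputs, writes every stage's
table, and records a manifest with input checksums and an exact count
reconciliation.

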