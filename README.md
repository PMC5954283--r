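# epivec

Sequence-only prediction of enhancer-promoter interactions (EPIs) from
paragraph-vector embeddings of DNA, for regulatory genomicists who want
to ask how much of 3D-contact specificity is readable from the element
sequences themselves.

Enhancers activate their target promoters across large genomic
distances, and which enhancer contacts which promoter is normally
established with chromatin-conformation experiments.  epivec treats
each enhancer or promoter sequence as a *sentence* whose words are its
overlapping k-mers: a sequence of length $L$ becomes
$T = \lfloor (L-k)/s \rfloor + 1$ tokens (defaults $k = 6$, $s = 1$,
vocabulary $4^6 = 4096$).  A distributed-memory paragraph-vector model
then learns one $d$-dimensional vector per k-mer and one per sequence
by maximizing

$$\sum_{i=1}^{N} \frac{1}{T_i-m} \sum_{t=1}^{T_i-m}
  \log p\left(c_{i,t+m} \mid w^{c_{i,t}},\dots,w^{c_{i,t+m-1}}, x_i\right),$$

the probability of each next word given its $m$-token context and the
sentence vector $x_i$, with a hierarchical softmax over a binary
Huffman tree (an exact softmax $y = b + Uh$ is provided as a reference
backend).  The trained sentence vectors are the sequence embedding
features.  Enhancers and promoters are embedded separately; a pair is
represented by the 200-dimensional concatenation of its two embeddings
(optionally extended with external experimental features) and
classified by gradient boosted regression trees
($\alpha = 10^{-3}$, $n = 4000$ trees, depth $D = 25$) under
stratified 10-fold cross-validation reporting F1 $= 2rp/(r+p)$, auROC
and auPRC.  Each k-mer of a sequence is scored for interpretability by
the attention softmax
$\alpha_{it} = \exp(x_i^\top w^{c_{i,t}}) / \sum_j \exp(x_i^\top w^{c_{i,j}})$,
and top-weighted k-mers can be exported as FASTA for motif-enrichment
tools.

A synthetic-benchmark generator with planted PWM motifs,
motif-compatibility-defined positive pairs and distance-binned negative
sampling (pair distances 10 kb - 2 Mb, five bins, one negative per
positive) provides ground-truth data for every stage; see the methods
vignette (`vignettes/epivec-methods.Rmd`) for the model, its
assumptions and the benchmark's calibration.

## Worked example

Simulate a small benchmark, embed both corpora, cross-validate the
pair classifier, and inspect the attention-selected k-mers:

```r
library(epivec)

spec <- syntheticSpec(nEnhancers = 120, nPromoters = 120,
                      nCandidatePairs = 200)
sim <- simulateDataset(spec, seed = 7)
sim$pairs
#> PairDataset: 78 pairs ( 39 positive / 39 negative )

enhCorp <- kmerCorpus(sim$enhancers)
enhCorp
#> KmerCorpus: 120 documents, 94609 tokens, V = 4096 (k = 6, s = 1)
#>   roles: enhancer:120

enhModel  <- trainEmbedding(enhCorp, trainConfig(seed = 8))
promModel <- trainEmbedding(kmerCorpus(sim$promoters, role = "promoter"),
                            trainConfig(seed = 9))

feats <- assembleFeatures(sim$pairs, enhModel, promModel)
feats
#> PairFeatures: 78 pairs x 200 features

report <- crossValidate(feats, gbrtConfig(nTrees = 400),
                        nFolds = 10, seed = 7)
report
#> CVReport over 10 stratified folds
#>   f1     0.7587 (sd 0.1834)
#>   auroc  0.7594 (sd 0.1874)
#>   auprc  0.7887 (sd 0.1493)

prof <- attentionProfiles(enhModel, enhCorp)
head(topKmers(prof, n = 1, positivesOnly = TRUE, dataset = sim$pairs), 3)
#>     kmer     doc_id    weight rank
#> 1 TGACTC ENHANCER_4 0.4526316    1
#> 2 CGTGTA ENHANCER_7 0.2261857    1
#> 3 CACGTG ENHANCER_9 0.1071881    1
```

The cross-validated F1 of 0.76 on this deliberately small example
rises above 0.8 at the default benchmark size (400 + 400 sequences,
~340 pairs, the full 4000-tree classifier).  The top attention k-mers
are instructive: `TGACTC` is the leading 6-mer of the planted "active"
enhancer motif (consensus `TGACTCAGCA`) and `CACGTG`/`CGTGTA` come
from the planted decoy (`CACGTGTTAC`) — the embeddings have organized
themselves around exactly the sequence features that drive the labels.

The same pipeline runs from the shell via the installed wrapper
(`inst/scripts/epivec.R`) with subcommands `simulate`, `embed`,
`infer`, `cv`, `predict` and `attend`; options follow
`--key value` with an optional flat `key=value` config file
(precedence CLI > file > defaults).  See `?epivecCLI`.

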