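Package: mutmil
Title: Attention-Based Multiple Instance Learning for Somatic Mutation Sets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for weakly supervised classification of tumour samples from
    their somatic mutation calls. A sample is modelled as a bag (set) of
    mutation instances; instances are featurized by genomic concepts (local
    sequence context, SBS96 trinucleotide category, genomic position bin,
    gene identity, reading frame), weighted by trainable multi-headed
    attention, aggregated by a permutation-invariant reduction (weighted
    mean, log-weighted-sum, or dynamic two-round attention) and classified
    end-to-end. Includes adaptive activation functions with trainable
    curvature, MIL-specific instance dropout, MAF reading and filtering with
    consecutive-SNV merging, synthetic bag-task generators for benchmarking,
    and interpretability utilities (attention z-scores, instance clustering,
    sequence logos and information content).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    Biostrings,
    IRanges,
    jsonlite,
    yaml,
    pROC
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
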