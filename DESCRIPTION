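Package: msccr
Title: Methyl-Sensitive Cut Counting (MSCC) Methylome Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for methyl-sensitive cut counting (MSCC) methylome
    profiling: virtual HpaII/MspI digestion of a reference genome into
    CCGG sites and 18-bp MmeI tag libraries, demultiplexing and
    mismatch-tolerant tag matching of dual-library sequencing reads,
    spike-in normalized per-site methylation quantification with depth
    filtering, window- and CpG-island-based differential methylation
    testing with Fisher's exact test, and descriptive genome-context
    analyses (metagene profiles, CGI/shore strata, histone-peak overlap,
    short-RNA proximity). A synthetic-data module generates toy genomes,
    ground-truth methylomes and simulated dual-library reads so every
    stage can be exercised and validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    stringr,
    ggplot2,
    generics,
    yaml,
    stats,
    tools,
    utils,
    Biostrings,
    BiocGenerics
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
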