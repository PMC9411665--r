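Package: equipain
Title: Movement Asymmetry, Pain-Scale Reliability and Diagnostic Accuracy in
    Equine Orthopedic Pain Studies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline linking orthopedic pain scored at rest to
    objectively measured movement asymmetry in trotting horses. Computes
    stride-segmented vertical asymmetry metrics (HDmin, PDmin) and the Total
    Asymmetry Score (TAS) from head and pelvis marker traces, models
    multi-observer scoring on four published equine pain scales, quantifies
    inter-observer agreement with the absolute-agreement intraclass
    correlation ICC(2,A1), fits penalized-spline mixed models of pain score
    versus asymmetry with a horse random intercept and AR(1) within-horse
    residuals, and evaluates diagnostic accuracy with ROC curves and DeLong
    confidence intervals. A synthetic-data generator emulating a
    lipopolysaccharide synovitis induction study makes every stage runnable
    and testable without access to real data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    signal,
    splines,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
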