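Package: tatbatch
Title: Optimal Batch-Waiting Intervals for Laboratory Task Switching
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for choosing an optimal task-switching (batch-waiting)
    interval in a clinical laboratory from sample event logs. A sample's
    three LIS timestamps (arrival at the laboratory, loading into the
    analyzer, and report to the hospital information system) are batched
    under a waiting interval M: samples accumulating within M minutes of an
    anchor sample's arrival are merged into a single analyzer-loading task.
    Sweeping M over a grid yields a trade-off curve between the number of
    loading tasks (a proxy for task-switching burden on technicians) and the
    turnaround-time (TAT) compliance rate; min-max normalization and
    weighted-sum scalarization select the optimal interval M0 together with
    the Pareto-optimal set. Includes a seeded synthetic event-log generator
    emulating emergency-room chemistry workloads, task-switch counting for
    labeled task sequences, duty-shift labeling, and reporting utilities
    (phase summaries, boxplot statistics, batch-deadline alert schedules).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ggplot2,
    stats,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
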