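# Deposited-style study data (not included)

This directory is a placeholder. The original study's deposited data are not
redistributable with this package and must be placed here manually to enable
the study-number reproduction checks in `tests/testthat/test-acceptance.R`
and `reproduce_study_analysis()`.

Expected layout (see `read_cohort()`):

    s1_file/
      <subject>_<modality>_run<k>.tsv   # node x time matrix, tab-separated,
                                        # no header; modality in {VV, AV, AA};
                                        # k in {1, 2}
      subjects.csv                      # columns: subject_id, age_months,
                                        # accuracy, latency_ms, pde

No data files ship in this directory; everything under `tests/` and the
acceptance script runs on synthetic cohorts generated in code.
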