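#' Miniature deterministic benchmark fixture
#'
#' Generates a small self-contained dataset for tests and documentation: a
#' 150-sample training stream (stimulus counts 40/50/20/20/20) and a 300-sample
#' testing stream (8 single-stimulus episodes) over 16 channels, simulated from
#' the default array model. The same seed regenerates bit-identical files.
#'
#' @param seed integer seed
#' @param dir output directory (created if needed); if `NULL`, nothing is
#'   written and the data are only returned
#' @return (invisibly) list with `train`, `test` (`response_matrix`) and, if
#'   `dir` was given, `files` (paths of `train.csv` and `test.csv`)
#' @export
make_fixture <- function(seed = 1L, dir = NULL) {
  cfg <- default_config()
  model <- config_model(cfg)
  tr_sch <- make_training_schedule(cfg$simulator$training_counts, seed = seed)
  te_sch <- make_testing_schedule(
    list(c(3, 35), c(1, 12), c(4, 60), c(2, 20), c(5, 80),
         c(4, 28), c(2, 10), c(5, 55)),
    first_episode_id = 1L, n_stimuli = 5L)
  full <- concat_schedules(tr_sch, te_sch)
  resp <- simulate_responses(model, full, seed = seed)
  out <- list(train = subset_samples(resp, seq_len(nrow(tr_sch))),
              test = subset_samples(resp, nrow(tr_sch) + seq_len(nrow(te_sch))))
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    files <- c(train = file.path(dir, "train.csv"),
               test = file.path(dir, "test.csv"))
    write_response_csv(out$train, files[["train"]])
    write_response_csv(out$test, files[["test"]])
    out$files <- files
  }
  invisible(out)
}
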