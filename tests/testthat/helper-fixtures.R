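# Shared fixtures, built in code. The tiny cohort is generated once per test
# run and reused read-only.

lab_matrix_from <- function(values, patients = NULL, labs = NULL) {
  if (is.null(patients)) patients <- rownames(values) %||% sprintf("p%d", seq_len(nrow(values)))
  if (is.null(labs)) labs <- colnames(values) %||% sprintf("lab%d", seq_len(ncol(values)))
  dimnames(values) <- list(patients, labs)
  labimpute:::new_lab_matrix(values)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

local({
  env <- topenv(environment())
  cache <- new.env(parent = emptyenv())
  assign("tiny_cohort", function() {
    if (is.null(cache$tiny)) {
      cache$tiny <- generate_cohort(default_spec("tiny"))
    }
    cache$tiny
  }, envir = env)
  assign("standard_cohort", function() {
    if (is.null(cache$standard)) {
      cache$standard <- generate_cohort(default_spec("standard"))
    }
    cache$standard
  }, envir = env)
  assign("tiny_qc_matrix", function() {
    if (is.null(cache$tiny_qc)) {
      co <- tiny_cohort()
      m <- suppressMessages(
        aggregate_median(co$lab_observations,
                         patients = co$truth$clusters$patient_id)
      )
      cache$tiny_qc <- suppressMessages(filter_outliers(m))$matrix
    }
    cache$tiny_qc
  }, envir = env)
})

# Independent adjusted Rand index used to score planted-cluster recovery.
ari <- function(a, b) mclust::adjustedRandIndex(a, b)

expect_tibble <- function(x) expect_s3_class(x, "tbl_df")
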