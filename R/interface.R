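## File I/O and the simulation-study harness.

#' Read a multi-environment bandit log from CSV
#'
#' Required columns: `y` (numeric outcome), `t` (integer treatment), `env`
#' (environment label), `prop` (recorded propensity); every remaining column
#' is a covariate. A header row is mandatory and no index column is allowed.
#'
#' @param path Path to the CSV file.
#' @return A [multienv_data()].
#' @export
read_multienv_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("y", "t", "env", "prop")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L)
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  covars <- setdiff(names(df), required)
  if (length(covars) == 0L)
    stop("no covariate columns found", call. = FALSE)
  bad <- which(!stats::complete.cases(df))
  if (length(bad) > 0L)
    stop("malformed rows (missing values) at line(s): ",
         paste(utils::head(bad + 1L, 10L), collapse = ", "), call. = FALSE)
  multienv_data(df$y, as.matrix(df[covars]), df$t, df$env, df$prop)
}

#' Write a multi-environment bandit log to CSV
#'
#' @param data A [multienv_data()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_multienv_csv <- function(data, path) {
  utils::write.csv(as.data.frame(data), path, row.names = FALSE)
  invisible(path)
}

#' Write a subset test result (or any result list) as JSON
#'
#' @param obj A `subset_test_result` or plain list.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_result_json <- function(obj, path) {
  jsonlite::write_json(unclass(obj), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Rejection-rate study of the effect-invariance tests
#'
#' Replays the simulation study design: for each combination of variant,
#' method, candidate subset and sample size, simulates replicate datasets
#' from the three-covariate latent-confounder model (two environments,
#' parameters freshly drawn Uniform[-3, 3] per replicate, logistic logging
#' policy) and records the empirical rejection rate at the given level with
#' its binomial standard error.
#'
#' @param config List with elements `variants` (default `"linear"`),
#'   `methods` (default `"wald"`), `subsets` (list of character vectors,
#'   default `list("x2")`), `ns` (default `c(1000, 2000)`), `n_rep`
#'   (default 100), `alpha` (default 0.05), `seed` (default 1),
#'   `dr_config` (options for the DR test).
#' @param out_csv Optional path; when given the table is also written as CSV.
#' @return Data frame with columns `variant`, `method`, `subset`, `n`,
#'   `rejection_rate`, `se`, `n_rep`.
#' @export
run_figure2_experiment <- function(config = list(), out_csv = NULL) {
  cfg <- utils::modifyList(list(variants = "linear", methods = "wald",
                                ns = c(1000L, 2000L),
                                n_rep = 100L, alpha = 0.05, seed = 1L,
                                dr_config = list(num_trees = 100L)), config)
  ## list-valued option replaced wholesale, never merged element-wise
  cfg$subsets <- if (is.null(config$subsets)) list("x2") else config$subsets
  rows <- list()
  for (variant in cfg$variants) for (method in cfg$methods)
    for (S in cfg$subsets) for (n in cfg$ns) {
      rej <- logical(cfg$n_rep)
      for (r in seq_len(cfg$n_rep)) {
        seed_r <- cfg$seed + 7919L * r + n
        params <- draw_example1_params(2L, seed = seed_r)
        sim <- simulate_example1(params, n_per_env = n %/% 2L,
                                 variant = variant, seed = seed_r + 1L)
        res <- if (method == "wald")
          wald_einv_test(sim$data, S, cfg$alpha)
        else dr_einv_test(sim$data, S, cfg$alpha,
                          utils::modifyList(cfg$dr_config,
                                            list(seed = seed_r + 2L)))
        rej[r] <- res$reject
      }
      rate <- mean(rej)
      rows[[length(rows) + 1L]] <- data.frame(
        variant = variant, method = method,
        subset = if (length(S) == 0L) "{}" else paste(S, collapse = ","),
        n = n, rejection_rate = rate,
        se = sqrt(rate * (1 - rate) / cfg$n_rep), n_rep = cfg$n_rep,
        stringsAsFactors = FALSE)
    }
  tab <- do.call(rbind, rows)
  if (!is.null(out_csv)) utils::write.csv(tab, out_csv, row.names = FALSE)
  tab
}
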