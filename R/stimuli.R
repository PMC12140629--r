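#' Context specification
#'
#' One stimulus context: a binary cue channel paired with a Gaussian
#' whisker-stimulus distribution.
#'
#' @param mu stimulus mean (stimulus units).
#' @param sigma stimulus standard deviation (> 0).
#' @param id integer context label; must be unique within a schedule.
#' @return a one-row data frame with columns `context_id`, `mu`, `sigma`.
#' @export
upe_context <- function(mu, sigma, id = 1L) {
  if (!is.numeric(sigma) || any(sigma <= 0))
    stop("invalid distribution: 'sigma' must be > 0")
  data.frame(context_id = as.integer(id), mu = mu, sigma = sigma)
}

as_contexts <- function(contexts) {
  if (is.null(contexts) || NROW(contexts) == 0L)
    stop("invalid argument: empty context list")
  if (!is.data.frame(contexts)) contexts <- do.call(rbind, contexts)
  if (is.null(contexts$context_id)) contexts$context_id <- seq_len(nrow(contexts))
  if (anyDuplicated(contexts$context_id))
    stop("context_id must be unique within an experiment")
  if (any(contexts$sigma <= 0))
    stop("invalid distribution: 'sigma' must be > 0")
  contexts[, c("context_id", "mu", "sigma")]
}

new_schedule <- function(df, contexts, duration, seed = NA_integer_) {
  rownames(df) <- NULL
  df$t <- seq_len(nrow(df))
  structure(df, contexts = contexts, duration = duration, seed = seed,
            class = c("upe_schedule", "data.frame"))
}

#' Gaussian context-cued stimulus schedule
#'
#' Draws `n_samples` i.i.d. samples per context from its Gaussian
#' distribution and holds each sample constant for `duration` timesteps
#' while the context's cue channel is on.  This sample-and-hold protocol
#' is the sole input every circuit consumes.
#'
#' @param contexts a data frame from [upe_context()] (rbind several rows
#'   for multiple contexts) or a list of such rows.
#' @param n_samples number of stimulus samples per context (N >= 1).
#' @param duration timesteps each sample is held (D >= 1); default 10.
#' @param seed integer seed; required, so schedules are reproducible.
#' @param interleave if `TRUE`, alternate single samples across contexts;
#'   default `FALSE` (blocked: each context's samples form one block).
#' @return an object of class `upe_schedule`: a data frame with columns
#'   `t`, `context_id`, `a`, `s`, `phase` and attributes `contexts`,
#'   `duration`, `seed`.
#' @export
#' @examples
#' sch <- upe_schedule(upe_context(5, 0.4), n_samples = 100, seed = 1)
#' nrow(sch)   # 100 * 10
upe_schedule <- function(contexts, n_samples, duration = 10, seed,
                         interleave = FALSE) {
  contexts <- as_contexts(contexts)
  if (missing(seed) || is.null(seed)) stop("'seed' is required")
  if (!is.numeric(n_samples) || n_samples < 1)
    stop("invalid argument: 'n_samples' must be >= 1")
  if (!is.numeric(duration) || duration < 1)
    stop("invalid argument: 'duration' must be >= 1")
  n_samples <- as.integer(n_samples); duration <- as.integer(duration)

  set.seed(as.integer(seed))
  draws <- lapply(seq_len(nrow(contexts)), function(i)
    rnorm(n_samples, contexts$mu[i], contexts$sigma[i]))

  if (interleave && nrow(contexts) > 1L) {
    ord <- data.frame(
      ctx = rep(seq_len(nrow(contexts)), times = n_samples),
      idx = rep(seq_len(n_samples), each = nrow(contexts)))
  } else {
    ord <- data.frame(ctx = rep(seq_len(nrow(contexts)), each = n_samples),
                      idx = rep(seq_len(n_samples), times = nrow(contexts)))
  }
  s_seq <- mapply(function(c, i) draws[[c]][i], ord$ctx, ord$idx)
  df <- data.frame(
    context_id = rep(contexts$context_id[ord$ctx], each = duration),
    a = 1.0,
    s = rep(s_seq, each = duration),
    phase = "train",
    stringsAsFactors = FALSE)
  new_schedule(df, contexts, duration, as.integer(seed))
}

#' Step-change stimulus schedule
#'
#' Concatenates training epochs that share a standard deviation but step
#' through a sequence of means, the protocol used to compare learning
#' speed after an abrupt change of the environment.  Epoch boundaries are
#' recorded in the phase tags (`"train.epoch1"`, `"train.epoch2"`, ...);
#' with a single mean the schedule reduces to [upe_schedule()] up to the
#' phase tag.
#'
#' @param means vector of epoch means (>= 2 for an actual step; a single
#'   mean is the degenerate one-epoch case).
#' @param sigma shared standard deviation (> 0).
#' @param samples_per_epoch samples per epoch.
#' @param duration timesteps each sample is held; default 10.
#' @param seed integer seed; required.
#' @param context_id cue channel carrying all epochs; default 1.
#' @return an `upe_schedule` whose `phase` column tags the epochs.
#' @export
upe_step_schedule <- function(means, sigma, samples_per_epoch,
                              duration = 10, seed, context_id = 1L) {
  if (missing(seed) || is.null(seed)) stop("'seed' is required")
  if (!is.numeric(means) || length(means) < 1)
    stop("invalid argument: 'means' must be nonempty")
  if (!is.numeric(sigma) || sigma <= 0)
    stop("invalid distribution: 'sigma' must be > 0")
  samples_per_epoch <- as.integer(samples_per_epoch)
  duration <- as.integer(duration)
  set.seed(as.integer(seed))
  parts <- lapply(seq_along(means), function(i) {
    s <- rnorm(samples_per_epoch, means[i], sigma)
    data.frame(context_id = as.integer(context_id), a = 1.0,
               s = rep(s, each = duration),
               phase = sprintf("train.epoch%d", i),
               stringsAsFactors = FALSE)
  })
  contexts <- data.frame(context_id = as.integer(context_id),
                         mu = means[length(means)], sigma = sigma)
  new_schedule(do.call(rbind, parts), contexts, duration, as.integer(seed))
}

#' Mismatch probe schedule
#'
#' Probe stimuli `s = mu_trained + deviation`, presented with the trained
#' context cue on and plasticity frozen (phase `"probe"`), used to read
#' out steady-state error responses after training.
#'
#' @param mu_trained the mean the circuit was trained on.
#' @param deviations vector of mismatches `s - mu` (may include 0).
#' @param duration timesteps per probe; default 1000 (long enough for the
#'   rates to settle at the default time constants).
#' @param context_id cue channel, matching the training context.
#' @return an `upe_schedule` with one probe block per deviation.
#' @export
upe_probe_schedule <- function(mu_trained, deviations, duration = 1000,
                               context_id = 1L) {
  if (length(deviations) == 0L)
    stop("invalid argument: empty deviation list")
  df <- data.frame(
    context_id = as.integer(context_id), a = 1.0,
    s = rep(mu_trained + deviations, each = as.integer(duration)),
    phase = "probe", stringsAsFactors = FALSE)
  contexts <- data.frame(context_id = as.integer(context_id),
                         mu = mu_trained, sigma = NA_real_)
  new_schedule(df, contexts, as.integer(duration))
}

#' Cue-only schedule
#'
#' The context cue alone, with no whisker stimulus (`s` absent): used to
#' read out the learned predictions (mean from SST or R, variance from
#' PV) without any teaching input.
#'
#' @param duration number of cue-only timesteps.
#' @param context_id cue channel; default 1.
#' @return an `upe_schedule` with phase `"cue"` and `s = NA`.
#' @export
upe_cue_schedule <- function(duration = 1000, context_id = 1L) {
  df <- data.frame(context_id = as.integer(context_id), a = 1.0,
                   s = NA_real_, phase = "cue", stringsAsFactors = FALSE)
  df <- df[rep(1L, as.integer(duration)), ]
  contexts <- data.frame(context_id = as.integer(context_id),
                         mu = NA_real_, sigma = NA_real_)
  new_schedule(df, contexts, as.integer(duration))
}

#' Concatenate schedules
#'
#' @param ... `upe_schedule` objects, in presentation order.
#' @return a single `upe_schedule`; the context table is the union.
#' @export
upe_cat_schedules <- function(...) {
  parts <- list(...)
  stopifnot(length(parts) > 0L)
  df <- do.call(rbind, lapply(parts, function(x) as.data.frame(x)))
  ctx <- unique(do.call(rbind, lapply(parts, attr, "contexts")))
  ctx <- ctx[!duplicated(ctx$context_id), ]
  new_schedule(df, ctx, attr(parts[[1L]], "duration"),
               attr(parts[[1L]], "seed"))
}

#' @export
print.upe_schedule <- function(x, ...) {
  ctx <- attr(x, "contexts")
  cat(sprintf("Stimulus schedule: %d timesteps, D = %d, %d context(s)\n",
              nrow(x), attr(x, "duration"), nrow(ctx)))
  ph <- table(x$phase)
  cat("  phases:", paste(sprintf("%s (%d)", names(ph), ph), collapse = ", "),
      "\n")
  if (!all(is.na(ctx$mu)))
    for (i in seq_len(nrow(ctx)))
      cat(sprintf("  context %d: mu = %s, sigma = %s\n", ctx$context_id[i],
                  format(ctx$mu[i]), format(ctx$sigma[i])))
  invisible(x)
}

#' Write / read a schedule as CSV
#'
#' Columns `t, context_id, a, s, phase`; values round-trip exactly at
#' full double precision.
#'
#' @param x an `upe_schedule`.
#' @param path file path.
#' @return `read_schedule` returns an `upe_schedule` (the context table
#'   is reconstructed from the data; `mu`/`sigma` are not stored in the
#'   CSV and are left `NA`).
#' @export
write_schedule <- function(x, path) {
  df <- as.data.frame(x)[, c("t", "context_id", "a", "s", "phase")]
  df$s <- sprintf("%.17g", df$s)
  df$s[df$s == "NA"] <- ""
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  df$s[df$s == ""] <- NA
  df$s <- as.numeric(df$s)
  ids <- unique(df$context_id)
  ctx <- data.frame(context_id = ids, mu = NA_real_, sigma = NA_real_)
  d <- rle(paste(df$s, df$context_id))$lengths
  new_schedule(df[, c("context_id", "a", "s", "phase")], ctx,
               duration = if (length(d)) min(d) else 1L)
}

# helper vectors for the compiled simulators
schedule_signals <- function(schedule) {
  ph <- schedule$phase
  list(ctx = as.integer(schedule$context_id),
       a = as.numeric(schedule$a),
       s = ifelse(is.na(schedule$s), 0.0, schedule$s),
       stim_on = !is.na(schedule$s),
       learn = startsWith(ph, "train"))
}
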