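# Synthetic multi-subject sensor data with known ground-truth shared
# structure. The generator emulates a two-group (intervention/control), two
# session (pre/post), two stimulus-version, four narrative-condition MEG
# design: within each design cell all subjects receive the same band-limited
# latent signal through subject-specific sensor mixing, plus independent
# sensor noise, at a controllable alignment strength (snr).

#' Generate a band-limited latent signal
#'
#' White Gaussian noise band-passed into `band` with the zero-phase FIR filter
#' of [bandpass()], then standardised to zero mean and unit variance. This
#' stands in for the stimulus-driven component shared across subjects.
#'
#' @param duration_s duration in seconds (> 0).
#' @param fs sampling rate in Hz; must exceed twice the upper band edge.
#' @param band length-2 numeric, pass-band in Hz (default `c(0.5, 10)`).
#' @param seed integer RNG seed; the series is deterministic given the seed.
#' @return object of class `latent_signal`: list with `samples` (numeric
#'   vector of length `round(duration_s * fs)`), `fs`, `band`.
#' @export
make_latent_signal <- function(duration_s, fs, band = c(0.5, 10), seed = 1L) {
  if (duration_s <= 0) stop("make_latent_signal: duration must be > 0")
  if (fs <= 2 * band[2]) {
    stop("make_latent_signal: fs must exceed twice the upper band edge (Nyquist)")
  }
  n <- as.integer(round(duration_s * fs))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  x <- stats::rnorm(n)
  x <- bandpass(x, fs, low = band[1], high = band[2])
  x <- (x - mean(x)) / stats::sd(x)
  structure(list(samples = x, fs = fs, band = band), class = "latent_signal")
}

# save/restore the global RNG state so generator calls do not perturb a
# caller's random stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Synthesize one subject's sensor recording
#'
#' Builds `snr * mixing %o% latent + noise`, with independent standard
#' Gaussian noise per channel. A channel with gain `g` therefore correlates
#' with the latent at the closed form `r = g*snr / sqrt(1 + (g*snr)^2)`, and
#' `snr = 0` yields pure noise.
#'
#' @param latent a `latent_signal` (or plain numeric vector).
#' @param mixing numeric vector of per-channel gains (the subject's forward
#'   model); length defines the channel count.
#' @param snr alignment strength: ratio of shared-signal to noise standard
#'   deviation (>= 0).
#' @param noise_seed integer seed for the subject's noise.
#' @return channels x time matrix.
#' @export
synthesize_subject <- function(latent, mixing, snr, noise_seed = 1L) {
  if (snr < 0) stop("synthesize_subject: snr must be >= 0")
  x <- if (inherits(latent, "latent_signal")) latent$samples else as.numeric(latent)
  nch <- length(mixing)
  if (nch < 1L || sum(mixing^2) == 0) {
    stop("synthesize_subject: mixing must have nonzero norm")
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(noise_seed)
  noise <- matrix(stats::rnorm(nch * length(x)), nrow = nch)
  snr * (mixing %o% x) + noise
}

# snr lookup for one design cell: base snr, plus delta_post for
# intervention-group political conditions in the post session only
cell_snr <- function(group, session, condition, base_snr, delta_post) {
  s <- base_snr
  if (group == "intervention" && session == "post" && grepl("^political", condition)) {
    s <- s + delta_post
  }
  s
}

#' Simulate a full group x session x version x condition study
#'
#' Generates one recording per (group, session, version, condition, subject).
#' Every subject of a group appears in all cells of that group; subject mixing
#' vectors (unit-norm Gaussian) are fixed across sessions and conditions, so
#' `snr` acts as the aggregate shared-to-noise amplitude ratio and the
#' ideal-filter intersubject correlation is `snr^2 / (1 + snr^2)` regardless
#' of channel count. One latent signal is drawn per (session, version,
#' condition) cell and shared by both groups (same stimuli); `delta_post` is
#' added to the snr of intervention-group political conditions in the post
#' session only. All randomness derives from `seed` through a counter scheme,
#' so the dataset is bit-reproducible.
#'
#' @param n_per_group subjects per group (>= 2).
#' @param n_channels sensor count (default 248).
#' @param duration_s recording length per condition in seconds (default 90).
#' @param fs sampling rate in Hz (default 400).
#' @param band latent pass-band in Hz (default `c(0.5, 10)`).
#' @param base_snr alignment strength applied to every cell (default 0.5).
#' @param delta_post snr increment for (intervention, post, political) cells.
#' @param snr_by_cell optional data.frame with columns `group`, `session`,
#'   `condition`, `snr` overriding the base/delta rule for listed cells.
#' @param snr_subject_sdlog log-normal spread of each recording's realised
#'   alignment strength around its cell value (default 0.6, about 65 percent
#'   coefficient of variation). This emulates the within-subject
#'   session-to-session variability of intersubject correlation seen in real
#'   data; it is the error term the paired pre/post contrasts rest on. Set to
#'   0 for perfectly homogeneous subjects.
#' @param seed master integer seed.
#' @return object of class `study_dataset`: `recordings` (named list of
#'   channels x time matrices), `index` (data.frame of cell labels per
#'   recording), `fs`, and `ground_truth` (latents per cell, per-subject
#'   mixing vectors, snr table).
#' @export
synthesize_study <- function(n_per_group, n_channels = 248, duration_s = 90,
                             fs = 400, band = c(0.5, 10), base_snr = 0.5,
                             delta_post = 0, snr_by_cell = NULL,
                             snr_subject_sdlog = 0.6, seed = 1L) {
  if (n_per_group < 2L) stop("synthesize_study: need at least 2 subjects per group")
  if (base_snr < 0 || (base_snr + delta_post) < 0) {
    stop("synthesize_study: snr values must be >= 0")
  }

  subjects <- lapply(.GROUPS, function(g) {
    sprintf("%s%02d", substr(g, 1, 3), seq_len(n_per_group))
  })
  names(subjects) <- .GROUPS

  # subject forward models: unit-norm Gaussian mixing, fixed across cells
  mixing <- list()
  ctr <- 0L
  for (g in .GROUPS) for (s in subjects[[g]]) {
    ctr <- ctr + 1L
    old <- .Random.seed_save()
    set.seed(derive_seed(seed, 1000L + ctr))
    v <- stats::rnorm(n_channels)
    .Random.seed_restore(old)
    mixing[[s]] <- v / sqrt(sum(v^2))
  }

  # latents per (session, version, condition) stimulus cell
  latents <- list()
  ctr <- 0L
  for (se in .SESSIONS) for (ve in .VERSIONS) for (co in .CONDITIONS) {
    ctr <- ctr + 1L
    latents[[paste(se, ve, co, sep = "|")]] <-
      make_latent_signal(duration_s, fs, band, seed = derive_seed(seed, 2000L + ctr))
  }

  lookup_snr <- function(g, se, co) {
    if (!is.null(snr_by_cell)) {
      hit <- snr_by_cell$group == g & snr_by_cell$session == se &
        snr_by_cell$condition == co
      if (any(hit)) return(snr_by_cell$snr[which(hit)[1]])
    }
    cell_snr(g, se, co, base_snr, delta_post)
  }

  recordings <- list()
  index <- list()
  snr_rows <- list()
  noise_ctr <- 0L
  for (g in .GROUPS) for (se in .SESSIONS) for (ve in .VERSIONS) for (co in .CONDITIONS) {
    lat <- latents[[paste(se, ve, co, sep = "|")]]
    s_cell <- lookup_snr(g, se, co)
    snr_rows[[length(snr_rows) + 1L]] <-
      data.frame(group = g, session = se, version = ve, condition = co, snr = s_cell)
    for (su in subjects[[g]]) {
      noise_ctr <- noise_ctr + 1L
      key <- rec_key(g, se, ve, co, su)
      s_real <- s_cell
      if (snr_subject_sdlog > 0) {
        old <- .Random.seed_save()
        set.seed(derive_seed(seed, 6000000L + noise_ctr))
        s_real <- s_cell * exp(stats::rnorm(1, 0, snr_subject_sdlog))
        .Random.seed_restore(old)
      }
      recordings[[key]] <- synthesize_subject(
        lat, mixing[[su]], s_real,
        noise_seed = derive_seed(seed, 3000000L + noise_ctr))
      index[[length(index) + 1L]] <- data.frame(
        group = g, session = se, version = ve, condition = co,
        subject = su, key = key, snr_realised = s_real)
    }
  }

  structure(list(
    recordings = recordings,
    index = do.call(rbind, index),
    fs = fs,
    ground_truth = list(
      latents = latents,
      mixing = mixing,
      snr = do.call(rbind, snr_rows),
      base_snr = base_snr,
      delta_post = delta_post,
      seed = seed
    )
  ), class = "study_dataset")
}

#' @export
print.study_dataset <- function(x, ...) {
  d <- dim(x$recordings[[1]])
  cat("study_dataset:", nrow(x$index), "recordings,",
      d[1], "channels x", d[2], "samples @", x$fs, "Hz\n")
  cat("  groups:", paste(unique(x$index$group), collapse = ", "), "\n")
  cat("  subjects/group:", length(unique(x$index$subject[x$index$group == x$index$group[1]])), "\n")
  invisible(x)
}

#' Mark random bad segments for each recording
#'
#' Draws, per recording, a small set of non-overlapping half-open intervals
#' totalling approximately `fraction` of the samples, to exercise the
#' zero-padding path of the preprocessing chain.
#'
#' @param dataset a `study_dataset`.
#' @param fraction fraction of samples to mask, in `[0, 0.5)`.
#' @param seed integer seed.
#' @return object of class `bad_segment_mask`: named list (by recording key)
#'   of two-column interval matrices (`start`, `end`, half-open, 1-based).
#' @export
mark_bad_segments <- function(dataset, fraction, seed = 1L) {
  stopifnot(inherits(dataset, "study_dataset"))
  if (fraction < 0 || fraction >= 0.5) {
    stop("mark_bad_segments: fraction must be in [0, 0.5)")
  }
  masks <- vector("list", length(dataset$recordings))
  names(masks) <- names(dataset$recordings)
  if (fraction == 0) {
    for (k in names(masks)) masks[[k]] <- matrix(integer(0), 0, 2)
    return(structure(masks, class = "bad_segment_mask"))
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(seed, 4000L))
  for (k in names(masks)) {
    t_len <- ncol(dataset$recordings[[k]])
    target <- round(fraction * t_len)
    n_seg <- if (target >= 3L) 3L else 1L
    lens <- diff(round(seq(0, target, length.out = n_seg + 1L)))
    lens <- lens[lens > 0]
    n_seg <- length(lens)
    free <- t_len - sum(lens)
    gaps <- sort(sample.int(free + 1L, n_seg, replace = TRUE)) - 1L
    starts <- gaps + c(0L, cumsum(lens[-n_seg])) + 1L
    masks[[k]] <- cbind(start = starts, end = starts + lens)
  }
  structure(masks, class = "bad_segment_mask")
}
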