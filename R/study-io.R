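# On-disk study container: a directory with a JSON attribute file and one
# full-precision CSV matrix per recording. Hierarchy is encoded in the file
# names (group|session|version|condition|subject) and mirrored in the index.

#' Write a study dataset to an on-disk container
#'
#' Lays out a `study_dataset` as a directory: `meta.json` (sampling rate,
#' recording index, ground-truth snr table and seed), `mixing.csv`
#' (per-subject forward models), `latents.csv` (one column per stimulus
#' cell), and `recordings/<key>.csv`, one channels x time matrix per
#' recording, written at full double precision.
#'
#' @param study a `study_dataset`.
#' @param path directory to create (must not already contain a container
#'   unless `overwrite = TRUE`).
#' @param overwrite logical, default FALSE.
#' @return `path`, invisibly.
#' @export
write_study <- function(study, path, overwrite = FALSE) {
  stopifnot(inherits(study, "study_dataset"))
  if (dir.exists(path) && file.exists(file.path(path, "meta.json")) && !overwrite) {
    stop("write_study: container already exists at ", path)
  }
  dir.create(file.path(path, "recordings"), recursive = TRUE, showWarnings = FALSE)
  gt <- study$ground_truth
  meta <- list(
    format = "mccalign-study/1",
    fs = study$fs,
    index = study$index,
    snr = gt$snr,
    base_snr = gt$base_snr,
    delta_post = gt$delta_post,
    seed = gt$seed,
    latent_band = gt$latents[[1]]$band,
    latent_cells = names(gt$latents)
  )
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  mix <- as.data.frame(gt$mixing)
  data.table::fwrite(mix, file.path(path, "mixing.csv"))
  lat <- as.data.frame(lapply(gt$latents, `[[`, "samples"), check.names = FALSE)
  data.table::fwrite(lat, file.path(path, "latents.csv"))
  for (k in names(study$recordings)) {
    fn <- file.path(path, "recordings", paste0(gsub("\\|", "__", k), ".csv"))
    data.table::fwrite(as.data.frame(study$recordings[[k]]), fn,
                       col.names = FALSE)
  }
  invisible(path)
}

#' Read a study dataset from an on-disk container
#'
#' @param path directory written by [write_study()].
#' @return a `study_dataset`.
#' @export
read_study <- function(path) {
  mf <- file.path(path, "meta.json")
  if (!file.exists(mf)) stop("read_study: no container at ", path)
  meta <- jsonlite::read_json(mf, simplifyVector = TRUE)
  if (!identical(meta$format, "mccalign-study/1")) {
    stop("read_study: unrecognised container format")
  }
  idx <- as.data.frame(meta$index)
  recordings <- vector("list", nrow(idx))
  names(recordings) <- idx$key
  for (k in idx$key) {
    fn <- file.path(path, "recordings", paste0(gsub("\\|", "__", k), ".csv"))
    recordings[[k]] <- as.matrix(data.table::fread(fn, header = FALSE))
    dimnames(recordings[[k]]) <- NULL
  }
  mix_df <- data.table::fread(file.path(path, "mixing.csv"))
  mixing <- lapply(as.list(mix_df), as.numeric)
  lat_df <- data.table::fread(file.path(path, "latents.csv"))
  band <- as.numeric(meta$latent_band)
  latents <- lapply(as.list(lat_df), function(x) {
    structure(list(samples = as.numeric(x), fs = meta$fs, band = band),
              class = "latent_signal")
  })
  structure(list(
    recordings = recordings,
    index = idx,
    fs = as.numeric(meta$fs),
    ground_truth = list(
      latents = latents, mixing = mixing,
      snr = as.data.frame(meta$snr),
      base_snr = meta$base_snr, delta_post = meta$delta_post,
      seed = meta$seed)
  ), class = "study_dataset")
}
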