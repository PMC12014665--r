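# Readers and writers: long-format CSV for epochs, sequences and picks,
# JSON sidecars for sampling metadata, and run manifests.

sidecar_path <- function(path) sub("\\.csv$", ".json", path)

#' Write / read raw epoch sets as long-format CSV with a JSON sidecar
#'
#' The CSV holds one row per sample
#' (\code{participant_id, sex, level, epoch_index, sample_index,
#' amplitude_uV}, plus \code{sequence_order}); the sidecar (same path with
#' a \code{.json} extension) records \code{sample_rate},
#' \code{onset_index} and \code{epochs_per_sequence}. The round-trip is
#' lossless.
#'
#' @param epoch_sets list of \code{vemp_epochs} objects.
#' @param path CSV path.
#' @param epochs_per_sequence recorded in the sidecar for downstream
#'   averaging.
#' @return \code{write_epochs()}: the path, invisibly; \code{read_epochs()}:
#'   a list of \code{vemp_epochs}.
#' @export
write_epochs <- function(epoch_sets, path, epochs_per_sequence = 300) {
  if (inherits(epoch_sets, "vemp_epochs")) epoch_sets <- list(epoch_sets)
  tabs <- lapply(epoch_sets, function(es) {
    n_ep <- nrow(es$epochs); n_s <- ncol(es$epochs)
    data.frame(
      participant_id = es$participant_id, sex = as.character(es$sex),
      level = es$stimulus_level,
      sequence_order = es$sequence_order %||% 1L,
      epoch_index = rep(seq_len(n_ep), each = n_s),
      sample_index = rep(seq_len(n_s), times = n_ep),
      amplitude_uV = as.numeric(t(es$epochs))
    )
  })
  utils::write.csv(do.call(rbind, tabs), path, row.names = FALSE)
  meta <- list(
    sample_rate = epoch_sets[[1]]$sample_rate,
    onset_index = epoch_sets[[1]]$onset_index,
    epochs_per_sequence = epochs_per_sequence
  )
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(path) {
  meta_path <- sidecar_path(path)
  if (!file.exists(meta_path))
    abort_schema(sprintf("missing JSON sidecar '%s' (sample_rate / onset metadata)",
                         meta_path))
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  for (f in c("sample_rate", "onset_index")) {
    if (is.null(meta[[f]])) abort_schema(paste("sidecar missing field:", f))
  }
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("participant_id", "sex", "level", "epoch_index", "sample_index",
            "amplitude_uV")
  miss <- setdiff(need, names(d))
  if (length(miss)) abort_schema(paste("missing columns:", paste(miss, collapse = ", ")))
  if (is.null(d$sequence_order)) d$sequence_order <- 1L
  key <- interaction(d$participant_id, d$level, d$sequence_order, drop = TRUE)
  lapply(split(d, key), function(g) {
    g <- g[order(g$epoch_index, g$sample_index), ]
    n_s <- max(g$sample_index)
    n_ep <- max(g$epoch_index)
    if (nrow(g) != n_s * n_ep)
      abort_schema("inconsistent epoch lengths in CSV")
    structure(list(
      participant_id = g$participant_id[1],
      sex = factor(g$sex[1], levels = c("female", "male")),
      stimulus_level = g$level[1],
      sample_rate = meta$sample_rate,
      onset_index = as.integer(meta$onset_index),
      sequence_order = as.integer(g$sequence_order[1]),
      epochs = matrix(g$amplitude_uV, n_ep, n_s, byrow = TRUE)
    ), class = "vemp_epochs")
  })
}

#' Write / read participant records of sequence averages
#'
#' CSV columns \code{participant_id, sex, level, sequence_order,
#' sample_index, value}; the JSON sidecar carries \code{sample_rate},
#' \code{onset_index}, the per-participant background EMG tension and
#' whether the values are normalised.
#'
#' @param records list of \code{vemp_record}s.
#' @param path CSV path.
#' @return \code{write_sequences()}: the path, invisibly;
#'   \code{read_sequences()}: a list of \code{vemp_record}s.
#' @export
write_sequences <- function(records, path) {
  if (inherits(records, "vemp_record")) records <- list(records)
  tabs <- lapply(records, function(r) {
    do.call(rbind, lapply(r$sequences, function(s) {
      data.frame(participant_id = s$participant_id,
                 sex = as.character(s$sex), level = s$stimulus_level,
                 sequence_order = s$sequence_order,
                 sample_index = seq_along(s$waveform),
                 value = s$waveform)
    }))
  })
  utils::write.csv(do.call(rbind, tabs), path, row.names = FALSE)
  first <- records[[1]]$sequences[[1]]
  meta <- list(
    sample_rate = first$sample_rate,
    onset_index = first$onset_index,
    normalized = isTRUE(records[[1]]$normalized),
    n_epochs = first$n_epochs,
    background_rms = stats::setNames(
      lapply(records, function(r) r$background_rms %||% NA),
      vapply(records, function(r) r$participant_id, "")
    )
  )
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_sequences
#' @export
read_sequences <- function(path) {
  meta_path <- sidecar_path(path)
  if (!file.exists(meta_path)) abort_schema(sprintf("missing JSON sidecar '%s'", meta_path))
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("participant_id", "sex", "level", "sequence_order",
            "sample_index", "value")
  miss <- setdiff(need, names(d))
  if (length(miss)) abort_schema(paste("missing columns:", paste(miss, collapse = ", ")))
  lapply(split(d, d$participant_id), function(g) {
    seqs <- lapply(split(g, g$sequence_order), function(s) {
      s <- s[order(s$sample_index), ]
      sq <- new_sequence(s$value, s$participant_id[1],
                         factor(s$sex[1], levels = c("female", "male")),
                         s$level[1], meta$sample_rate,
                         as.integer(meta$onset_index),
                         s$sequence_order[1],
                         meta$n_epochs %||% NA_integer_,
                         normalized = isTRUE(meta$normalized))
      sq
    })
    bg <- meta$background_rms[[g$participant_id[1]]]
    structure(list(
      participant_id = g$participant_id[1],
      sex = factor(g$sex[1], levels = c("female", "male")),
      truth = NULL, sequences = unname(seqs),
      background_rms = if (!is.null(bg) && !is.na(bg)) bg else NULL,
      normalized = isTRUE(meta$normalized)
    ), class = "vemp_record")
  })
}

#' Write / read pick tables
#'
#' Latencies are serialised in ms with 4 decimal places; stimulus levels as
#' integers.
#'
#' @param picks data frame from [pick_cohort()].
#' @param path CSV path.
#' @return \code{write_picks()}: the path, invisibly; \code{read_picks()}:
#'   the pick data frame.
#' @export
write_picks <- function(picks, path) {
  out <- picks
  for (col in c("p1_latency", "n1_latency", "p1n1_latency",
                "p1n1_amplitude", "response_level")) {
    out[[col]] <- round(out[[col]], 4)
  }
  out$stimulus_level <- as.integer(round(out$stimulus_level))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_picks
#' @export
read_picks <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("participant_id", "sex", "stimulus_level", "p1_latency",
            "n1_latency", "p1n1_latency", "p1n1_amplitude",
            "response_level", "is_null")
  miss <- setdiff(need, names(d))
  if (length(miss)) abort_schema(paste("missing columns:", paste(miss, collapse = ", ")))
  d$sex <- factor(d$sex, levels = c("female", "male"))
  d
}

#' Run manifest
#'
#' Metadata describing a pipeline stage run: configuration snapshot, seed,
#' timings, file paths and package version; written next to each emitted
#' artifact.
#'
#' @param stage stage name.
#' @param config \code{vemp_config} or \code{NULL}.
#' @param seed integer seed or \code{NULL}.
#' @param inputs,outputs character vectors of paths.
#' @param elapsed elapsed seconds.
#' @return list of class \code{vemp_manifest}.
#' @export
run_manifest <- function(stage, config = NULL, seed = NULL,
                         inputs = character(), outputs = character(),
                         elapsed = NA_real_) {
  structure(list(
    stage = stage,
    package_version = as.character(utils::packageVersion("cvemp")),
    seed = seed,
    config = if (!is.null(config)) unclass(config),
    inputs = inputs, outputs = outputs,
    elapsed_seconds = elapsed
  ), class = "vemp_manifest")
}

write_manifest <- function(manifest, out_path) {
  jsonlite::write_json(unclass(manifest), paste0(out_path, ".manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(manifest)
}
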