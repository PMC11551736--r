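#' Write and read trace tables as tab-separated text
#'
#' One file per condition. Intensity traces get columns `trace_id`,
#' `time_s`, `intensity`; FRET traces get `trace_id`, `time_s`, `donor`,
#' `acceptor`.
#'
#' @param traces list of `nisp_trace` or `fret_trace` objects.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trace_table <- function(traces, path) {
  if (!length(traces)) {
    utils::write.table(
      data.frame(trace_id = integer(), time_s = numeric(),
                 intensity = numeric()),
      path, sep = "\t", row.names = FALSE, quote = FALSE)
    return(invisible(path))
  }
  is_fret <- inherits(traces[[1]], "fret_trace")
  tabs <- lapply(seq_along(traces), function(i) {
    tr <- traces[[i]]
    if (is_fret)
      data.frame(trace_id = i, time_s = tr$times, donor = tr$donor,
                 acceptor = tr$acceptor)
    else
      data.frame(trace_id = i, time_s = tr$times, intensity = tr$intensities)
  })
  utils::write.table(do.call(rbind, tabs), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trace_table
#' @param meta optional metadata list attached to every trace read back.
#' @export
read_trace_table <- function(path, meta = NULL) {
  d <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  if (!nrow(d)) return(list())
  is_fret <- all(c("donor", "acceptor") %in% names(d))
  lapply(split(d, factor(d$trace_id, levels = unique(d$trace_id))),
         function(dd) {
    if (is_fret)
      new_fret_trace(dd$time_s, dd$donor, dd$acceptor, truth = NULL,
                     meta = meta)
    else
      new_trace(dd$time_s, dd$intensity, truth = NULL, meta = meta)
  })
}

#' Write a benchmark set to a directory (trace tables + manifest)
#'
#' @param bench a [generate_benchmark_set()] result.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_benchmark_set <- function(bench, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- bench$manifest
  if (nrow(manifest)) {
    manifest$file <- paste0("traces_", manifest$condition, ".tsv")
    for (i in seq_len(nrow(manifest)))
      write_trace_table(bench$traces[[manifest$condition[i]]],
                        file.path(dir, manifest$file[i]))
  }
  utils::write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' @rdname write_benchmark_set
#' @export
read_benchmark_set <- function(dir) {
  manifest <- utils::read.delim(file.path(dir, "manifest.tsv"), sep = "\t",
                                stringsAsFactors = FALSE)
  traces <- list()
  for (i in seq_len(nrow(manifest))) {
    meta <- as.list(manifest[i, ])
    meta$condition <- manifest$condition[i]
    traces[[manifest$condition[i]]] <-
      read_trace_table(file.path(dir, manifest$file[i]), meta = meta)
  }
  structure(list(traces = traces, manifest = manifest),
            class = "benchmark_set")
}
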