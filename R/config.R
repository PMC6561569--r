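#' Pipeline configuration
#'
#' Collects every numeric threshold used across the pipeline in one object
#' so that a run is fully described by its config and its inputs. Defaults
#' follow common practice for transcriptome-derived duplication analyses:
#' DUST low-complexity cutoff 7 over 64-base windows, transcripts of at
#' least 500 bp with TPM of at least 1, isoform clustering at 100 bp overlap
#' and 97 percent identity, alignment rows dropped above 1,500 residues or
#' 40 percent gaps, a 50-gene synteny window requiring 2 shared paralogue
#' families, and paralogue-age histograms over 0.2--1.4 4dTv units.
#'
#' @param dust_threshold maximum DUST score for a transcript to pass.
#' @param dust_window window size (bases) for the DUST score.
#' @param min_transcript_len minimum transcript length in bases (inclusive).
#' @param min_tpm minimum expression in transcripts per million (inclusive).
#' @param isoform_min_overlap minimum aligned overlap (bases) for two
#'   transcripts to be considered isoforms of one gene.
#' @param isoform_min_identity minimum identity fraction for isoform matches.
#' @param max_protein_len proteins strictly longer than this are dropped.
#' @param max_gap_frac alignment rows with a gap fraction strictly above
#'   this are dropped.
#' @param synteny_window number of neighbouring genes examined on each side
#'   of a paralogue.
#' @param min_shared_families shared neighbour families required to call
#'   conserved synteny.
#' @param min_4d_sites minimum qualifying fourfold sites for a pair's 4dTv
#'   to be reported as defined.
#' @param hist_min,hist_max histogram range in 4dTv units.
#' @param hist_width histogram bin width in 4dTv units.
#' @param mixture_k_candidates integer vector of mixture component counts
#'   scored by BIC.
#' @param rng_seed integer seed recorded with the run.
#' @return an object of class `wgdtv_config` (a validated named list).
#' @examples
#' cfg <- pipeline_config(synteny_window = 25)
#' cfg$synteny_window
#' @export
pipeline_config <- function(dust_threshold = 7,
                            dust_window = 64,
                            min_transcript_len = 500,
                            min_tpm = 1,
                            isoform_min_overlap = 100,
                            isoform_min_identity = 0.97,
                            max_protein_len = 1500,
                            max_gap_frac = 0.40,
                            synteny_window = 50,
                            min_shared_families = 2,
                            min_4d_sites = 10,
                            hist_min = 0.2,
                            hist_max = 1.4,
                            hist_width = 0.05,
                            mixture_k_candidates = 1:4,
                            rng_seed = 1L) {
  cfg <- list(
    dust_threshold = dust_threshold,
    dust_window = as.integer(dust_window),
    min_transcript_len = as.integer(min_transcript_len),
    min_tpm = min_tpm,
    isoform_min_overlap = as.integer(isoform_min_overlap),
    isoform_min_identity = isoform_min_identity,
    max_protein_len = as.integer(max_protein_len),
    max_gap_frac = max_gap_frac,
    synteny_window = as.integer(synteny_window),
    min_shared_families = as.integer(min_shared_families),
    min_4d_sites = as.integer(min_4d_sites),
    hist_min = hist_min,
    hist_max = hist_max,
    hist_width = hist_width,
    mixture_k_candidates = as.integer(mixture_k_candidates),
    rng_seed = as.integer(rng_seed)
  )
  class(cfg) <- "wgdtv_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "wgdtv_config"))
  num <- c("dust_threshold", "dust_window", "min_transcript_len", "min_tpm",
           "isoform_min_overlap", "isoform_min_identity", "max_protein_len",
           "max_gap_frac", "synteny_window", "min_shared_families",
           "min_4d_sites", "hist_min", "hist_max", "hist_width")
  for (f in num) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v))
      stop("config field '", f, "' must be a single number", call. = FALSE)
  }
  pos <- setdiff(num, "max_gap_frac")
  for (f in pos) if (cfg[[f]] <= 0)
    stop("config field '", f, "' must be strictly positive", call. = FALSE)
  if (cfg$isoform_min_identity > 1)
    stop("isoform_min_identity must lie in (0, 1]", call. = FALSE)
  if (cfg$max_gap_frac < 0 || cfg$max_gap_frac > 1)
    stop("max_gap_frac must lie in [0, 1]", call. = FALSE)
  if (cfg$hist_min >= cfg$hist_max)
    stop("hist_min must be smaller than hist_max", call. = FALSE)
  if (length(cfg$mixture_k_candidates) < 1L ||
      any(cfg$mixture_k_candidates < 1L))
    stop("mixture_k_candidates must be positive integers", call. = FALSE)
  invisible(cfg)
}

#' @export
print.wgdtv_config <- function(x, ...) {
  cat("wgdtv pipeline configuration\n")
  for (f in names(x)) {
    cat(sprintf("  %-22s %s\n", f, paste(x[[f]], collapse = ",")))
  }
  invisible(x)
}

#' Read or write a pipeline configuration file
#'
#' Configs are stored as flat INI-style `key = value` text files, one field
#' per line; `mixture_k_candidates` is comma-separated. Unknown keys are an
#' error so that typos do not silently fall back to defaults.
#'
#' @param path file path.
#' @return for `read_config`, a `wgdtv_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) != 2L
  if (any(bad))
    stop("malformed config line: ", lines[which(bad)[1]], call. = FALSE)
  keys <- trimws(vapply(kv, `[[`, "", 1L))
  vals <- trimws(vapply(kv, `[[`, "", 2L))
  known <- names(formals(pipeline_config))
  unknown <- setdiff(keys, known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  args <- lapply(seq_along(keys), function(i) {
    as.numeric(strsplit(vals[i], ",", fixed = TRUE)[[1]])
  })
  names(args) <- keys
  do.call(pipeline_config, args)
}

#' @rdname read_config
#' @param cfg a `wgdtv_config` object.
#' @export
write_config <- function(cfg, path) {
  validate_config(cfg)
  lines <- vapply(names(cfg), function(f) {
    sprintf("%s = %s", f, paste(format(cfg[[f]], scientific = FALSE),
                                collapse = ","))
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Line-oriented run log
#'
#' Messages go to stderr and, when `logfile` is set via `log_to`, are
#' appended to that file as well.
#'
#' @param ... message parts, pasted together.
#' @keywords internal
log_msg <- function(...) {
  msg <- paste0("[wgdtv ", format(Sys.time(), "%H:%M:%S"), "] ", ...)
  message(msg)
  lf <- getOption("wgdtv.logfile")
  if (!is.null(lf)) cat(msg, "\n", file = lf, append = TRUE, sep = "")
  invisible(msg)
}

#' @rdname log_msg
#' @param path log file path, or NULL to disable file logging.
#' @export
log_to <- function(path) {
  options(wgdtv.logfile = path)
  invisible(path)
}
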