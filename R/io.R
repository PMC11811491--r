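# Session-log and parameter serialization. JSONL is the canonical session
# format (one record per line, nulls where a field is not observed); CSV is
# a flattened spreadsheet view with x_0..x_{M-1} columns. All floating
# point is serialized at 17 significant digits so round trips are
# bit-faithful.

fmt_num <- function(x) {
  ifelse(is.na(x), NA_character_, sprintf("%.17g", x))
}

session_records <- function(ss) {
  n <- length(ss$time)
  lapply(seq_len(n), function(i) {
    list(child_id = ss$child_id, t = ss$time[i],
         x = as.numeric(ss$features[i, ]),
         intervention = if (is.na(ss$intervention[i])) NULL
                        else ss$intervention[i],
         engagement = if (is.na(ss$engagement[i])) NULL else ss$engagement[i],
         confidence = if (is.na(ss$confidence[i])) NULL else ss$confidence[i],
         intensity = if (is.na(ss$intensity[i])) NULL else ss$intensity[i])
  })
}

#' Write sessions to a JSONL or CSV log
#'
#' JSONL: one record per line with fields `child_id`, `t`, `x` (array),
#' `intervention`, `engagement`, `confidence`, `intensity`; absent values
#' are JSON nulls. CSV: the same records with `x` flattened into
#' `x_0..x_{M-1}` columns and empty cells for absent values.
#'
#' @param sessions A `sen_session`, a list of them, or a `sen_cohort`.
#' @param path Output path.
#' @param format `"jsonl"` or `"csv"`; default inferred from the file
#'   extension (`.csv` -> csv, anything else jsonl).
#' @return `path`, invisibly.
#' @export
write_sessions <- function(sessions, path, format = NULL) {
  if (inherits(sessions, "sen_session")) sessions <- list(sessions)
  if (is.null(format)) {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "jsonl"
  }
  format <- match.arg(format, c("jsonl", "csv"))
  if (format == "jsonl") {
    con <- file(path, open = "wb")
    on.exit(close(con))
    for (ss in sessions) {
      for (rec in session_records(ss)) {
        line <- jsonlite::toJSON(rec, digits = NA, auto_unbox = TRUE,
                                 null = "null")
        writeLines(line, con, sep = "\n")
      }
    }
  } else {
    M <- ncol(sessions[[1]]$features)
    rows <- lapply(sessions, function(ss) {
      n <- length(ss$time)
      xcols <- apply(ss$features, 2L, fmt_num)
      if (n == 1L) xcols <- matrix(xcols, nrow = 1L)
      colnames(xcols) <- sprintf("x_%d", seq_len(M) - 1L)
      cbind(data.frame(child_id = ss$child_id, t = fmt_num(ss$time),
                       stringsAsFactors = FALSE),
            as.data.frame(xcols, stringsAsFactors = FALSE),
            data.frame(intervention = ss$intervention,
                       engagement = fmt_num(ss$engagement),
                       confidence = fmt_num(ss$confidence),
                       intensity = fmt_num(ss$intensity),
                       stringsAsFactors = FALSE))
    })
    utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                     na = "")
  }
  invisible(path)
}

rebuild_session <- function(child_id, recs) {
  n <- length(recs)
  M <- length(recs[[1]]$x)
  X <- matrix(0, n, M)
  time <- numeric(n)
  interv <- rep(NA_character_, n)
  eng <- rep(NA_real_, n); conf <- rep(NA_real_, n); inten <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    r <- recs[[i]]
    time[i] <- r$t
    X[i, ] <- r$x
    if (!is.null(r$intervention) && !is.na(r$intervention)) {
      interv[i] <- r$intervention
    }
    if (!is.null(r$engagement)) eng[i] <- r$engagement
    if (!is.null(r$confidence)) conf[i] <- r$confidence
    if (!is.null(r$intensity)) inten[i] <- r$intensity
  }
  if (n > 1L && any(diff(time) <= 0)) {
    stop(sprintf("times not strictly increasing for child '%s'", child_id),
         call. = FALSE)
  }
  structure(list(child_id = child_id, seed = NA_integer_, time = time,
                 features = X, intervention = interv, engagement = eng,
                 confidence = conf, intensity = inten,
                 reward = rep(NA_real_, n), n_clipped = NA_integer_),
            class = "sen_session")
}

#' Read sessions from a JSONL or CSV log
#'
#' Inverse of [write_sessions()]: consecutive records sharing a `child_id`
#' form one session. Malformed lines and per-child cue-length
#' inconsistencies raise an error naming the offending line.
#'
#' @param path Input path.
#' @param format `"jsonl"` or `"csv"`; default inferred from the extension.
#' @return A list of `sen_session` objects (empty list for an empty file).
#' @export
read_sessions <- function(path, format = NULL) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path),
                               call. = FALSE)
  if (is.null(format)) {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "jsonl"
  }
  format <- match.arg(format, c("jsonl", "csv"))
  recs <- list()
  if (format == "jsonl") {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    recs <- lapply(seq_along(lines), function(i) {
      r <- tryCatch(jsonlite::fromJSON(lines[i], simplifyVector = TRUE),
                    error = function(e) {
                      stop(sprintf("malformed JSONL at line %d: %s",
                                   i, conditionMessage(e)), call. = FALSE)
                    })
      if (is.null(r$child_id) || is.null(r$t) || is.null(r$x)) {
        stop(sprintf("missing required field at line %d", i), call. = FALSE)
      }
      r$x <- as.numeric(r$x)
      r
    })
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE,
                          colClasses = "character")
    xcols <- grep("^x_[0-9]+$", names(df), value = TRUE)
    xcols <- xcols[order(as.integer(sub("^x_", "", xcols)))]
    recs <- lapply(seq_len(nrow(df)), function(i) {
      num <- function(v) if (is.na(v) || v == "") NA_real_ else as.numeric(v)
      list(child_id = df$child_id[i], t = as.numeric(df$t[i]),
           x = vapply(unlist(df[i, xcols]), num, numeric(1),
                      USE.NAMES = FALSE),
           intervention = if (is.na(df$intervention[i]) ||
                              df$intervention[i] == "") NULL
                          else df$intervention[i],
           engagement = {e <- num(df$engagement[i]); if (is.na(e)) NULL else e},
           confidence = {e <- num(df$confidence[i]); if (is.na(e)) NULL else e},
           intensity = {e <- num(df$intensity[i]); if (is.na(e)) NULL else e})
    })
  }
  if (length(recs) == 0L) return(list())
  ids <- vapply(recs, function(r) r$child_id, character(1))
  mlen <- vapply(recs, function(r) length(r$x), integer(1))
  run_id <- cumsum(c(TRUE, ids[-1L] != ids[-length(ids)]))
  for (g in split(seq_along(recs), run_id)) {
    if (length(unique(mlen[g])) != 1L) {
      bad <- g[which(mlen[g] != mlen[g[1L]])[1L]]
      stop(sprintf("inconsistent cue-vector length at line %d (child '%s')",
                   bad, ids[bad]), call. = FALSE)
    }
  }
  unname(lapply(split(seq_along(recs), run_id), function(g) {
    rebuild_session(ids[g[1L]], recs[g])
  }))
}

#' Write model parameters to a versioned JSON document
#'
#' Serializes [latent_params()] or [transition_params()] (matrices as
#' nested row-major arrays) with a schema tag; [read_params()] restores the
#' exact object.
#'
#' @param params A `sen_latent_params` or `sen_transition_params`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_params <- function(params, path) {
  schema <- if (inherits(params, "sen_latent_params")) {
    "senadapt/latent-params/v1"
  } else if (inherits(params, "sen_transition_params")) {
    "senadapt/transition-params/v1"
  } else stop("unsupported parameter object", call. = FALSE)
  doc <- c(list(schema = schema), unclass(params))
  jsonlite::write_json(doc, path, digits = NA, auto_unbox = TRUE,
                       pretty = TRUE, matrix = "rowmajor")
  invisible(path)
}

#' Read model parameters from JSON
#'
#' @param path File written by [write_params()].
#' @return The restored parameter object.
#' @export
read_params <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_mat <- function(m) if (is.matrix(m)) m else rbind(m)
  if (identical(doc$schema, "senadapt/latent-params/v1")) {
    latent_params(M = doc$M, D = doc$D,
                  encoder_w = as_mat(doc$encoder_w),
                  encoder_b = as.numeric(doc$encoder_b),
                  decay_A = as_mat(doc$decay_A), decay_rho = doc$decay_rho,
                  gate_w = as_mat(doc$gate_w),
                  gate_b = as.numeric(doc$gate_b),
                  noise_sd = doc$noise_sd)
  } else if (identical(doc$schema, "senadapt/transition-params/v1")) {
    transition_params(D = doc$D, M = doc$M,
                      state_w = as_mat(doc$state_w),
                      state_b = as.numeric(doc$state_b),
                      input_w = as_mat(doc$input_w),
                      input_b = as.numeric(doc$input_b),
                      attn_w = as_mat(doc$attn_w),
                      attn_b = as.numeric(doc$attn_b),
                      decay_c0 = doc$decay_c0, decay_c1 = doc$decay_c1,
                      reg_lambda = doc$reg_lambda, noise_sd = doc$noise_sd,
                      attention_renorm = doc$attention_renorm)
  } else stop("unrecognized parameter schema", call. = FALSE)
}

#' Write a run manifest
#'
#' Records everything needed to reproduce an artifact: package version,
#' the effective configuration, the seed, and md5 digests of any input
#' files. Deliberately timestamp-free so manifests themselves are
#' byte-reproducible.
#'
#' @param path Manifest output path.
#' @param config Effective configuration list.
#' @param seed Seed used.
#' @param inputs Character vector of input file paths to digest.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, config, seed, inputs = character()) {
  digests <- if (length(inputs)) {
    d <- as.character(tools::md5sum(inputs))
    names(d) <- basename(inputs)
    as.list(d)
  } else NULL
  doc <- list(tool = "senadapt",
              version = as.character(utils::packageVersion("senadapt")),
              seed = seed, config = config, input_digests = digests)
  jsonlite::write_json(doc, path, digits = NA, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}
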