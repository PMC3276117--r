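# Tab-separated readers and writers. All files are UTF-8 TSV with a
# mandatory header row; "." marks a missing value.

read_tsv_checked <- function(path, needed, what) {
  if (!file.exists(path)) stop(what, " file not found: ", path)
  df <- tryCatch(
    utils::read.delim(path, stringsAsFactors = FALSE, colClasses = "character"),
    error = function(e) stop("malformed ", what, " file '", path, "': ",
                             conditionMessage(e))
  )
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols)) {
    stop(what, " file '", path, "' lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  df
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = ".")
  invisible(path)
}

num_col <- function(x, col, path) {
  v <- suppressWarnings(as.numeric(x))
  if (anyNA(v) && !all(is.na(v) == (x == "."))) {
    bad <- which(is.na(v) & x != ".")[1]
    stop("file '", path, "', column ", col, ", data line ", bad,
         ": not a number ('", x[bad], "')")
  }
  v
}

#' Read / write a sites table
#'
#' TSV columns: `site_id`, `site_type`, `alphabet` (comma-joined, empty for
#' ICN), `max_total_copies`, `max_allele_copies`.
#'
#' @param path File path.
#' @return [read_sites()]: a [cnv_sites()] table.
#' @export
read_sites <- function(path) {
  df <- read_tsv_checked(path, c("site_id", "site_type", "alphabet",
                                 "max_total_copies", "max_allele_copies"),
                         "sites")
  df$alphabet[is.na(df$alphabet) | df$alphabet == "."] <- ""
  df$max_total_copies <- as.integer(num_col(df$max_total_copies,
                                            "max_total_copies", path))
  df$max_allele_copies <- as.integer(num_col(df$max_allele_copies,
                                             "max_allele_copies", path))
  validate_sites(df)
}

#' @param sites A [cnv_sites()] table.
#' @rdname read_sites
#' @export
write_sites <- function(sites, path) {
  write_tsv(as.data.frame(validate_sites(sites)), path)
}

#' Read / write a GenoSpectrum table
#'
#' TSV columns: `individual_id`, `site_id`, `state`, `likelihood`. Missing
#' (individual, site) combinations are filled in downstream by
#' [missing_call_spectrum()].
#'
#' @param path File path.
#' @return [read_genospectrum()]: a [geno_spectrum()] table.
#' @export
read_genospectrum <- function(path) {
  df <- read_tsv_checked(path, c("individual_id", "site_id", "state",
                                 "likelihood"), "spectrum")
  df$likelihood <- num_col(df$likelihood, "likelihood", path)
  validate_spectrum(df)
}

#' @param spectra A [geno_spectrum()] table.
#' @rdname read_genospectrum
#' @export
write_genospectrum <- function(spectra, path) {
  write_tsv(as.data.frame(validate_spectrum(spectra)), path)
}

#' Read / write a haplotype frequency table
#'
#' TSV columns: `haplotype`, `frequency`; rows sorted by descending
#' frequency (ties by haplotype string).
#'
#' @param path File path.
#' @return [read_frequencies()]: a [freq_table()].
#' @export
read_frequencies <- function(path) {
  df <- read_tsv_checked(path, c("haplotype", "frequency"), "frequency")
  freq_table(stats::setNames(num_col(df$frequency, "frequency", path),
                             df$haplotype))
}

#' @param freqs A [freq_table()].
#' @rdname read_frequencies
#' @export
write_frequencies <- function(freqs, path) {
  ord <- order(-as.numeric(freqs), names(freqs), method = "radix")
  write_tsv(data.frame(haplotype = names(freqs)[ord],
                       frequency = as.numeric(freqs)[ord]), path)
}

#' Read / write diplotype calls
#'
#' TSV columns: `individual_id`, `diplotype` (canonical `h1/h2`, `.` for a
#' no-call), `proportion`, then one implied-state column per site (named by
#' `site_id`).
#'
#' @param called A [call_diplotypes()] result.
#' @param sites The [cnv_sites()] table (for implied per-site states).
#' @param path File path.
#' @export
write_diplotype_calls <- function(called, sites, path) {
  out <- called[, c("individual_id", "diplotype", "proportion")]
  states <- matrix(NA_character_, nrow(called), nrow(sites),
                   dimnames = list(NULL, sites$site_id))
  ok <- called$called & !is.na(called$diplotype)
  if (any(ok)) {
    states[ok, ] <- collapse_diplotypes(called$h1[ok], called$h2[ok], sites)
  }
  write_tsv(cbind(out, as.data.frame(states, stringsAsFactors = FALSE)), path)
}

#' @rdname write_diplotype_calls
#' @export
read_diplotype_calls <- function(path) {
  df <- read_tsv_checked(path, c("individual_id", "diplotype", "proportion"),
                         "diplotype calls")
  df$proportion <- num_col(df$proportion, "proportion", path)
  df$diplotype[df$diplotype == "."] <- NA_character_
  df$called <- !is.na(df$diplotype)
  sp <- split_diplotype(ifelse(df$called, df$diplotype, "./."))
  df$h1 <- ifelse(df$called, sp$h1, NA_character_)
  df$h2 <- ifelse(df$called, sp$h2, NA_character_)
  df
}

#' Read / write a Gaussian signal model
#'
#' TSV columns: `site_id`, `state`, `mean` (comma-joined channel means),
#' `covariance` (row-major comma-joined). The package works with spherical
#' covariances; reading a non-spherical matrix is an error.
#'
#' @param path File path.
#' @return [read_signal_model()]: a `signal_model`.
#' @export
read_signal_model <- function(path) {
  df <- read_tsv_checked(path, c("site_id", "state", "mean", "covariance"),
                         "signal model")
  comps <- split(df, df$site_id)
  model <- lapply(comps, function(sub) {
    means <- do.call(rbind, lapply(strsplit(sub$mean, ",", fixed = TRUE),
                                   as.numeric))
    d <- ncol(means)
    sds <- vapply(strsplit(sub$covariance, ",", fixed = TRUE), function(v) {
      m <- matrix(as.numeric(v), d, d)
      if (!isTRUE(all.equal(m, diag(m[1, 1], d), tolerance = 1e-8))) {
        stop("non-spherical covariance in '", path,
             "'; only sigma^2 * I is supported")
      }
      sqrt(m[1, 1])
    }, 0)
    if (length(unique(round(sds, 12))) != 1L) {
      stop("per-state sd differs within site ", sub$site_id[1],
           " in '", path, "'; a common per-site sd is required")
    }
    rownames(means) <- sub$state
    list(site_id = sub$site_id[1], states = sub$state, means = means,
         sd = sds[1])
  })
  structure(model[unique(df$site_id)], class = "signal_model")
}

#' @param model A `signal_model`.
#' @rdname read_signal_model
#' @export
write_signal_model <- function(model, path) {
  rows <- lapply(model, function(comp) {
    d <- ncol(comp$means)
    covs <- paste(rep(as.vector(diag(comp$sd^2, d)), 1), collapse = ",")
    data.frame(
      site_id = comp$site_id,
      state = comp$states,
      mean = apply(comp$means, 1, paste, collapse = ","),
      covariance = vapply(seq_along(comp$states), function(i) {
        paste(as.vector(diag(comp$sd^2, d)), collapse = ",")
      }, ""),
      stringsAsFactors = FALSE
    )
  })
  write_tsv(do.call(rbind, rows), path)
}

#' Read / write signal measurements
#'
#' TSV columns: `individual_id`, `site_id`, `value` (comma-joined channel
#' values).
#'
#' @param path File path.
#' @param sites A [cnv_sites()] table fixing site order.
#' @return [read_signals()]: a `signal_data` list of matrices.
#' @export
read_signals <- function(path, sites) {
  df <- read_tsv_checked(path, c("individual_id", "site_id", "value"),
                         "measurements")
  out <- lapply(sites$site_id, function(sid) {
    sub <- df[df$site_id == sid, , drop = FALSE]
    if (!nrow(sub)) stop("no measurements for site ", sid, " in '", path, "'")
    m <- do.call(rbind, lapply(strsplit(sub$value, ",", fixed = TRUE),
                               as.numeric))
    rownames(m) <- sub$individual_id
    m
  })
  names(out) <- sites$site_id
  structure(out, class = "signal_data")
}

#' @param signals A `signal_data` object.
#' @rdname read_signals
#' @export
write_signals <- function(signals, path) {
  rows <- lapply(names(signals), function(sid) {
    x <- signals[[sid]]
    data.frame(
      individual_id = rownames(x),
      site_id = sid,
      value = apply(x, 1, paste, collapse = ","),
      stringsAsFactors = FALSE
    )
  })
  write_tsv(do.call(rbind, rows), path)
}

#' Write / read a truth table of diplotypes
#'
#' TSV columns: `individual_id`, `h1`, `h2`.
#'
#' @param truth `data.frame` with `individual_id`, `h1`, `h2`.
#' @param path File path.
#' @export
write_truth <- function(truth, path) {
  write_tsv(truth[, c("individual_id", "h1", "h2")], path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  read_tsv_checked(path, c("individual_id", "h1", "h2"), "truth")
}

#' Read a simulation configuration from YAML
#'
#' Keys: `n_individuals`, `seed`, and either `scenario` (a [sim_scenario()]
#' name) or explicit `frequencies` (map haplotype -> frequency, normalized
#' on read) plus `sites` (list of maps with the [cnv_sites()] fields);
#' optional `target_miscall`, `spacing`, `n_replicates`.
#'
#' @param path YAML file path.
#' @return List with `freqs`, `sites`, `n_individuals`, `seed`,
#'   `target_miscall`, `spacing`, `n_replicates`.
#' @export
read_sim_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$scenario)) {
    sc <- sim_scenario(cfg$scenario)
    freqs <- sc$freqs
    sites <- sc$sites
    target <- if (is.null(cfg$target_miscall)) sc$target_miscall else cfg$target_miscall
  } else {
    if (is.null(cfg$frequencies) || is.null(cfg$sites)) {
      stop("config must give either 'scenario' or both 'frequencies' and 'sites'")
    }
    freqs <- freq_table(unlist(cfg$frequencies), normalize = TRUE)
    sdf <- do.call(rbind, lapply(cfg$sites, function(s) {
      data.frame(site_id = s$site_id, site_type = s$site_type,
                 alphabet = if (is.null(s$alphabet)) "" else s$alphabet,
                 max_total_copies = if (is.null(s$max_total_copies)) 4L else s$max_total_copies,
                 max_allele_copies = if (is.null(s$max_allele_copies)) 2L else s$max_allele_copies,
                 stringsAsFactors = FALSE)
    }))
    sites <- validate_sites(sdf)
    target <- if (is.null(cfg$target_miscall)) 0.22 else cfg$target_miscall
  }
  if (is.null(cfg$n_individuals)) stop("config lacks n_individuals")
  list(
    freqs = freqs,
    sites = sites,
    n_individuals = as.integer(cfg$n_individuals),
    seed = as.integer(if (is.null(cfg$seed)) 1L else cfg$seed),
    target_miscall = target,
    spacing = if (is.null(cfg$spacing)) 1 else cfg$spacing,
    n_replicates = as.integer(if (is.null(cfg$n_replicates)) 1L else cfg$n_replicates)
  )
}
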