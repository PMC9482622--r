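#' Write / read a cohort table
#'
#' Cohorts are stored as UTF-8 comma-delimited text with a header row and
#' `NA` for missing entries; domain labels travel in a companion
#' `<path>.domains` two-column file so a read-back cohort keeps its feature
#' domain map.
#'
#' @param cohort a [simulate_cohort()] cohort.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  write.csv(as.data.frame(cohort), path, row.names = FALSE, quote = FALSE,
            fileEncoding = "UTF-8")
  domains <- attr(cohort, "domains")
  if (!is.null(domains))
    write.csv(data.frame(feature = names(domains), domain = unname(domains)),
              paste0(path, ".domains"), row.names = FALSE, quote = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  cohort <- read.csv(path, fileEncoding = "UTF-8")
  dpath <- paste0(path, ".domains")
  if (file.exists(dpath)) {
    d <- read.csv(dpath, fileEncoding = "UTF-8")
    attr(cohort, "domains") <- stats::setNames(d$domain, d$feature)
  }
  class(cohort) <- c("cohort", "data.frame")
  cohort
}

#' Write / read a connectome stack
#'
#' One comma-delimited square matrix per subject plus a `manifest.csv`
#' listing the per-subject files and a `modules.csv` node-community map.
#'
#' @param stack a [generate_connectomes()] stack.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_connectomes <- function(stack, dir) {
  stopifnot(inherits(stack, "connectome_stack"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- sprintf("subject_%03d.csv", seq_along(stack$matrices))
  for (i in seq_along(stack$matrices))
    utils::write.table(stack$matrices[[i]], file.path(dir, files[i]),
                       sep = ",", row.names = FALSE, col.names = FALSE)
  write.csv(data.frame(subject = seq_along(files), file = files),
            file.path(dir, "manifest.csv"), row.names = FALSE, quote = FALSE)
  write.csv(data.frame(node = seq_along(stack$module),
                       module = stack$module),
            file.path(dir, "modules.csv"), row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' @rdname write_connectomes
#' @export
read_connectomes <- function(dir) {
  manifest <- read.csv(file.path(dir, "manifest.csv"))
  mats <- lapply(manifest$file, function(f)
    as.matrix(utils::read.table(file.path(dir, f), sep = ",")))
  mats <- lapply(mats, function(M) {
    dimnames(M) <- list(paste0("node_", seq_len(nrow(M))),
                        paste0("node_", seq_len(nrow(M))))
    M
  })
  module <- read.csv(file.path(dir, "modules.csv"))$module
  structure(list(matrices = mats, module = module),
            class = "connectome_stack")
}

#' Write / read an effect specification as plain-text key-value pairs
#'
#' @param spec an [effect_spec()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_effect_spec <- function(spec, path) {
  stopifnot(inherits(spec, "effect_spec"))
  kv <- c(
    sprintf("beta.%s=%.17g", names(spec$beta), spec$beta),
    sprintf("gamma.%s=%.17g", names(spec$gamma), spec$gamma),
    sprintf("beta_sex=%.17g", spec$beta_sex),
    sprintf("sigma_f=%.17g", spec$sigma_f),
    sprintf("sigma_e=%.17g", spec$sigma_e),
    if (!is.null(spec$tau)) sprintf("tau=%s", paste(sprintf("%.17g", spec$tau),
                                                    collapse = ",")),
    if (!is.null(spec$tau_dep)) sprintf("tau_dep=%.17g", spec$tau_dep),
    sprintf("prevalence=%.17g", spec$prevalence),
    sprintf("use_probs=%s", paste(sprintf("%.17g", spec$use_probs),
                                  collapse = ","))
  )
  writeLines(kv, path)
  invisible(path)
}

#' @rdname write_effect_spec
#' @export
read_effect_spec <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  keys <- sub("=.*$", "", lines)
  vals <- sub("^[^=]*=", "", lines)
  getv <- function(k, default = NULL) {
    i <- which(keys == k)
    if (!length(i)) return(default)
    as.numeric(strsplit(vals[i], ",")[[1]])
  }
  pick_named <- function(prefix) {
    i <- which(startsWith(keys, paste0(prefix, ".")))
    stats::setNames(as.numeric(vals[i]),
                    sub(paste0("^", prefix, "\\."), "", keys[i]))
  }
  effect_spec(beta = pick_named("beta"), gamma = pick_named("gamma"),
              beta_sex = getv("beta_sex", 0), sigma_f = getv("sigma_f", 0.5),
              sigma_e = getv("sigma_e", 1), tau = getv("tau"),
              tau_dep = if (length(getv("tau_dep"))) getv("tau_dep"),
              prevalence = getv("prevalence", 109 / 1204),
              use_probs = getv("use_probs",
                               c(550, 324, 144, 78, 108) / 1204))
}
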