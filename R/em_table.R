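#' Membrane-potential table for one experimental condition
#'
#' Mean membrane potential (with SEM and replicate count) at each external
#' K+ concentration, for one condition (genotype x capacitation state x pH x
#' blocker x media). This is the unit of data the GHK fits consume.
#'
#' @param K_out external K+ concentrations, mM.
#' @param Em_mean mean membrane potentials, mV.
#' @param Em_sem standard errors of the mean, mV (`NA` allowed when n = 1).
#' @param n replicate counts.
#' @param condition optional [condition_spec()] (or plain label string)
#'   attached as the `"condition"` attribute.
#' @return An `"em_table"`: a data frame with columns `K_out`, `Em_mean`,
#'   `Em_sem`, `n`.
#' @export
em_table <- function(K_out, Em_mean, Em_sem = NA_real_, n = NA_integer_,
                     condition = NULL) {
  d <- data.frame(K_out = as.numeric(K_out), Em_mean = as.numeric(Em_mean),
                  Em_sem = as.numeric(Em_sem), n = as.integer(n))
  if (any(!is.finite(d$K_out)) || any(d$K_out <= 0))
    stop("K_out values must be positive and finite", call. = FALSE)
  if (anyDuplicated(d$K_out))
    stop("K_out values must be distinct", call. = FALSE)
  if (any(!is.finite(d$Em_mean)))
    stop("Em_mean values must be finite", call. = FALSE)
  bad <- !is.na(d$Em_sem) & !is.na(d$n) & d$n > 1L & d$Em_sem <= 0
  if (any(bad))
    stop("Em_sem must be > 0 when n > 1", call. = FALSE)
  d <- d[order(d$K_out), , drop = FALSE]
  rownames(d) <- NULL
  structure(d, condition = condition, class = c("em_table", "data.frame"))
}

#' @export
print.em_table <- function(x, ...) {
  cond <- attr(x, "condition")
  cat("Em table", if (!is.null(cond)) paste0(" [", condition_label(cond), "]"),
      ":\n", sep = "")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

condition_label <- function(condition) {
  if (is.null(condition)) return("unlabelled")
  if (is.character(condition)) return(condition)
  if (inherits(condition, "condition_spec")) return(format(condition))
  "unlabelled"
}

#' Read membrane-potential tables from CSV
#'
#' Expects columns `condition`, `K_out_mM`, `Em_mV`, `sem_mV`, `n`, and
#' optionally the condition descriptors `genotype`, `state`, `pH`,
#' `blocker`, `media` (written by [write_em_tables()]); when the
#' descriptors are present each table carries a full [condition_spec()],
#' so staged fits can apply condition-appropriate constraints.
#'
#' @param path CSV file path.
#' @return Named list of `em_table` objects, one per distinct `condition`.
#' @export
read_em_tables <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("condition", "K_out_mM", "Em_mV")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  if (is.null(d$sem_mV)) d$sem_mV <- NA_real_
  if (is.null(d$n)) d$n <- NA_integer_
  desc <- c("genotype", "state", "pH", "blocker", "media")
  out <- lapply(split(d, d$condition), function(g) {
    cond <- if (all(desc %in% names(d)) && !anyNA(unlist(g[1, desc])))
      condition_spec(genotype = g$genotype[1], state = g$state[1],
                     pH = as.character(g$pH[1]), blocker = g$blocker[1],
                     media = g$media[1])
    else g$condition[1]
    em_table(g$K_out_mM, g$Em_mV, g$sem_mV, g$n, condition = cond)
  })
  out[unique(d$condition)]
}

#' Write membrane-potential tables to CSV
#'
#' Inverse of [read_em_tables()]; `condition` labels are taken from the
#' list names or the tables' condition attributes.
#'
#' @param tables a named list of [em_table()] objects (or a single table).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_em_tables <- function(tables, path) {
  if (inherits(tables, "em_table")) tables <- list(tables)
  if (is.null(names(tables)))
    names(tables) <- vapply(tables, function(t)
      condition_label(attr(t, "condition")), character(1))
  rows <- lapply(names(tables), function(nm) {
    t <- tables[[nm]]
    out <- data.frame(condition = nm, K_out_mM = t$K_out, Em_mV = t$Em_mean,
                      sem_mV = t$Em_sem, n = t$n)
    cond <- attr(t, "condition")
    if (inherits(cond, "condition_spec")) {
      out$genotype <- cond$genotype; out$state <- cond$state
      out$pH <- cond$pH; out$blocker <- cond$blocker; out$media <- cond$media
    }
    out
  })
  cols <- unique(unlist(lapply(rows, names)))
  rows <- lapply(rows, function(r) {
    r[setdiff(cols, names(r))] <- NA
    r[cols]
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
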