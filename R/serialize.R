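# TSV serializers for reference states and capacity tables, used by the
# command-line interface and for replaying fixtures from files.

#' Read/write a reference state as TSV
#'
#' Columns: `reaction_id`, `SSL`, `SSU`; measured fluxes and the wild-type
#' biomass maximum travel in comment header lines (`# measured ...`,
#' `# vbiomass_max ...`).
#'
#' @param ref a [reference_state()].
#' @param path file path.
#' @return `write_reference_state`: `path`, invisibly;
#'   `read_reference_state`: a [reference_state()].
#' @export
write_reference_state <- function(ref, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(ref$measured))
    writeLines(paste("# measured", paste(names(ref$measured), ref$measured,
                                         sep = "=", collapse = " ")), con)
  if (!is.null(ref$vbiomass_max))
    writeLines(paste("# vbiomass_max", ref$vbiomass_max), con)
  utils::write.table(
    data.frame(reaction_id = names(ref$SSU), SSL = unname(ref$SSL),
               SSU = unname(ref$SSU)),
    con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_reference_state
#' @export
read_reference_state <- function(path) {
  lines <- readLines(path)
  headers <- lines[startsWith(lines, "#")]
  measured <- numeric(0)
  vbmax <- NULL
  for (h in headers) {
    toks <- strsplit(trimws(sub("^#", "", h)), "[[:space:]]+")[[1]]
    if (toks[1] == "measured") {
      kv <- strsplit(toks[-1], "=", fixed = TRUE)
      measured <- stats::setNames(as.numeric(vapply(kv, `[`, "", 2)),
                                  vapply(kv, `[`, "", 1))
    } else if (toks[1] == "vbiomass_max") {
      vbmax <- as.numeric(toks[2])
    }
  }
  tab <- utils::read.delim(text = lines[!startsWith(lines, "#")])
  reference_state(stats::setNames(tab$SSU, tab$reaction_id),
                  stats::setNames(tab$SSL, tab$reaction_id),
                  measured = measured, vbiomass_max = vbmax)
}

#' Read/write a capacity set as TSV
#'
#' One row per reaction/direction. Parametric rows carry `location`,
#' `scale`, `lower`, `upper`; empirical rows carry the sample inlined as a
#' comma-separated `values` field.
#'
#' @param caps a capacity set (named lists `up`, `down`).
#' @param path file path.
#' @return `write_capacity_set`: `path`, invisibly; `read_capacity_set`: a
#'   capacity set.
#' @export
write_capacity_set <- function(caps, path) {
  rows <- list()
  for (dir in c("up", "down")) {
    for (d in caps[[dir]]) {
      rows[[length(rows) + 1L]] <- if (d$kind == "truncnorm") {
        data.frame(reaction_id = d$reaction_id, direction = d$direction,
                   kind = "truncnorm", location = d$location, scale = d$scale,
                   lower = d$lower, upper = d$upper, values = "")
      } else {
        data.frame(reaction_id = d$reaction_id, direction = d$direction,
                   kind = "empirical", location = NA, scale = NA,
                   lower = NA, upper = NA,
                   values = paste(format(d$values, digits = 15, trim = TRUE),
                                  collapse = ","))
      }
    }
  }
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_capacity_set
#' @export
read_capacity_set <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  caps <- list(up = list(), down = list())
  for (i in seq_len(nrow(tab))) {
    d <- if (tab$kind[i] == "truncnorm") {
      capacity_parametric(tab$reaction_id[i], tab$direction[i],
                          tab$location[i], tab$scale[i],
                          tab$lower[i], tab$upper[i])
    } else {
      capacity_empirical(tab$reaction_id[i], tab$direction[i],
                         as.numeric(strsplit(tab$values[i], ",")[[1]]),
                         min_sample = 1)
    }
    caps[[tab$direction[i]]][[tab$reaction_id[i]]] <- d
  }
  structure(caps, class = "capacity_set")
}

result_to_list <- function(res) {
  out <- list(status = res$status)
  if (res$status == "optimal") {
    out$interventions <- list(up = res$interventions$up,
                              down = res$interventions$down)
    out$v_target <- res$v_target
    out$objective <- res$objective
    out$fluxes <- as.list(res$fluxes)
  }
  out$eps <- res$eps
  out$alpha <- res$alpha
  out
}
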