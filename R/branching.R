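#' Prechemical branching table
#'
#' Maps each primary-event class (ionization of a water molecule, or one of
#' the excitation channels) to the radiolytic products it dissociates into
#' by 1 ps, with a sampling probability per channel and a per-product radial
#' displacement scale (nm) modelling dissociation kick and, for the solvated
#' electron, thermalization distance.
#'
#' @param df data frame with columns `class` (event class), `channel`
#'   (channel label), `prob`, `products` (list column of character vectors)
#'   and `scales` (list column of numeric vectors, one per product, nm).
#' @param class_probs named numeric vector of event-class probabilities
#'   (must sum to 1).
#' @param species a [species_table()] to validate products against.
#' @return a `branching_table` data frame with a `class_probs` attribute.
#' @export
branching_table <- function(df, class_probs, species = default_species()) {
  need <- c("class", "channel", "prob", "products", "scales")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("branching table is missing columns: ", paste(miss, collapse = ", "))
  df <- as.data.frame(df)
  if (!is.list(df$products) || !is.list(df$scales))
    stop("`products` and `scales` must be list columns")
  for (i in seq_len(nrow(df))) {
    bad <- setdiff(df$products[[i]], species$species)
    if (length(bad) > 0)
      stop("branching channel '", df$channel[i], "' produces unknown species: ",
           paste(bad, collapse = ", "))
    if (length(df$scales[[i]]) != length(df$products[[i]]))
      stop("branching channel '", df$channel[i],
           "': one displacement scale per product is required")
    if (any(df$scales[[i]] < 0))
      stop("branching channel '", df$channel[i],
           "': displacement scales must be >= 0")
  }
  for (cl in unique(df$class)) {
    s <- sum(df$prob[df$class == cl])
    if (abs(s - 1) > 1e-9)
      stop("channel probabilities for event class '", cl,
           "' sum to ", s, ", not 1")
  }
  if (is.null(names(class_probs)) || abs(sum(class_probs) - 1) > 1e-9)
    stop("`class_probs` must be a named vector summing to 1")
  miss <- setdiff(unique(df$class), names(class_probs))
  if (length(miss) > 0)
    stop("no class probability given for: ", paste(miss, collapse = ", "))
  rownames(df) <- NULL
  attr(df, "class_probs") <- class_probs
  class(df) <- c("branching_table", "data.frame")
  df
}

#' Default prechemical branching
#'
#' Literature-style placeholder ratios (the published branching data of the
#' track-structure codes are not reproduced here): every ionization yields
#' `{OH, H3O+, e_aq}`; excitations dissociate to `{OH, H}` (p = 0.5) or
#' `{H2, 2 OH}` (p = 0.15) or relax without radical production (p = 0.35).
#' Event classes are ionization (p = 0.72) and excitation (p = 0.28).
#' Displacement scales: 0.8 nm for heavy fragments, 4 nm for electron
#' thermalization.
#'
#' @param species a [species_table()].
#' @return a `branching_table`.
#' @export
default_branching <- function(species = default_species()) {
  df <- data.frame(
    class = c("ionization", "excitation", "excitation", "excitation"),
    channel = c("ion_dissoc", "exc_oh_h", "exc_h2_2oh", "exc_relax"),
    prob = c(1, 0.5, 0.15, 0.35),
    stringsAsFactors = FALSE
  )
  df$products <- list(c("OH", "H3O+", "e_aq"),
                      c("OH", "H"),
                      c("H2", "OH", "OH"),
                      character(0))
  df$scales <- list(c(0.8, 0.8, 4.0),
                    c(0.8, 0.8),
                    c(0.8, 0.8, 0.8),
                    numeric(0))
  branching_table(df, c(ionization = 0.72, excitation = 0.28), species)
}

# expected 1-ps products per event, by species: used by tests and for the
# quick yield estimates in the documentation
branching_expectation <- function(branching, species = default_species()) {
  cp <- attr(branching, "class_probs")
  out <- setNames(numeric(nrow(species)), species$species)
  for (i in seq_len(nrow(branching))) {
    w <- cp[[branching$class[i]]] * branching$prob[i]
    for (p in branching$products[[i]]) out[p] <- out[p] + w
  }
  out
}
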