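# Independent brute-force oracle: enumerate elementary flux modes of small
# networks by support-set search over the internal (non-exchange) reactions,
# and predict the crowding-constrained optimum as the best
# objective-per-crowding-cost ratio times the budget. Deliberately naive and
# fully separate from the package's LP path.

# Null space of a matrix via SVD.
oracle_nullspace <- function(A, tol = 1e-9) {
  k <- ncol(A)
  sv <- svd(A, nu = 0, nv = k)
  d <- c(sv$d, rep(0, k - length(sv$d)))
  sv$v[, d < tol * max(1, d[1]), drop = FALSE]
}

# Enumerate elementary modes: support-minimal steady-state flux patterns over
# the internal reactions (assumed irreversible), with exchanged metabolites
# free up to the sign allowed by their exchange bounds.
oracle_modes <- function(model, tol = 1e-9) {
  S <- as.matrix(stoichiometry(model))
  rxn <- reactionBounds(model)
  exch <- grepl("^(R_)?EX_|^DM_", rxn$id) | colSums(S != 0) == 1
  internal <- rxn$id[!exch]
  stopifnot(length(internal) <= 12)
  exchMet <- rownames(S)[rowSums(S[, exch, drop = FALSE] != 0) > 0]
  balMet <- setdiff(rownames(S), exchMet)
  objMet <- rownames(S)[S[, objectiveReaction(model)] != 0]
  modes <- list()
  for (k in seq_along(internal)) {
    for (J in utils::combn(length(internal), k, simplify = FALSE)) {
      kernel <- oracle_nullspace(S[balMet, internal[J], drop = FALSE], tol)
      if (ncol(kernel) != 1) next
      v <- kernel[, 1]
      if (all(v <= tol)) v <- -v
      if (any(v < tol)) next # sign-infeasible or support smaller than J
      sup <- internal[J]
      smaller <- vapply(modes, function(mm) all(mm$support %in% sup), logical(1))
      if (any(smaller)) next # not support-minimal
      prod <- drop(S[exchMet, sup, drop = FALSE] %*% v)
      names(prod) <- exchMet
      feasible <- TRUE
      for (met in exchMet) {
        ex_id <- rxn$id[exch][S[met, exch] != 0]
        if (!length(ex_id)) {
          if (abs(prod[met]) > tol) feasible <- FALSE
          next
        }
        lb <- rxn$lower_bound[match(ex_id[1], rxn$id)]
        ub <- rxn$upper_bound[match(ex_id[1], rxn$id)]
        # exchange coefficient is -1: net production leaves as efflux
        if (prod[met] > tol && ub <= tol) feasible <- FALSE
        if (prod[met] < -tol && lb >= -tol) feasible <- FALSE
      }
      if (!feasible) next
      modes[[length(modes) + 1]] <- list(
        flux = stats::setNames(v, sup), support = sup,
        production = prod, objective = unname(prod[objMet]))
    }
  }
  modes
}

# Best objective-per-crowding-cost ratio times the budget: the predicted
# crowding-limited optimum at unconstrained glucose influx.
oracle_optimum <- function(model, assignment, vProt, modes = NULL) {
  if (is.null(modes)) modes <- oracle_modes(model)
  coefs <- crowdingCoefficients(assignment)
  best <- 0
  for (mm in modes) {
    if (mm$objective <= 0) next
    cost <- sum(coefs[mm$support] * mm$flux)
    if (cost <= 0) next
    best <- max(best, vProt * mm$objective / cost)
  }
  best
}

# ATP yields per glucose of the objective-producing modes, normalized to
# unit glucose consumption.
oracle_mode_yields <- function(model, glucoseMet = "glc") {
  modes <- oracle_modes(model)
  out <- vapply(modes, function(mm) {
    gup <- -mm$production[glucoseMet]
    if (is.na(gup) || gup <= 1e-9) return(NA_real_)
    mm$objective / gup
  }, numeric(1))
  sort(out[!is.na(out) & out > 1e-9])
}
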