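# Independent oracles used across the suite. Each is deliberately written
# with a different mechanism than the implementation it checks.

# Peak window by enumeration: list every candidate boundary index that
# satisfies the rule, then take the nearest one on each side of the core
# super-threshold run containing the global maximum.
oraclePeak <- function(y, thr, rule = "local_min_at_or_below") {
    n <- length(y)
    if (!any(y > thr)) return(NULL)
    apex <- which(y == max(y))[1L]
    runs <- rle(y > thr)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    k <- which(starts <= apex & ends >= apex & runs$values)
    cs <- starts[k]; ce <- ends[k]
    isCandidate <- vapply(seq_len(n), function(i) {
        if (y[i] > thr) return(FALSE)
        if (rule == "first_at_or_below") return(TRUE)
        (i == 1L || y[i] <= y[i - 1L]) && (i == n || y[i] <= y[i + 1L])
    }, logical(1))
    lc <- which(isCandidate)[which(isCandidate) < cs]
    rc <- which(isCandidate)[which(isCandidate) > ce]
    iL <- if (length(lc)) max(lc) else 1L
    iR <- if (length(rc)) min(rc) else n
    list(iLeft = iL, iRight = iR, iApex = apex,
         edgeTruncated = length(lc) == 0L || length(rc) == 0L,
         response = sum(y[iL:iR]))
}

# Two-sided exact Mann-Whitney p by full enumeration of all C(na+nb, na)
# group assignments of the pooled values (no ties assumed).
oracleMannWhitney <- function(a, b) {
    x <- c(a, b)
    na <- length(a)
    Uobs <- sum(outer(a, b, ">"))
    idx <- utils::combn(length(x), na)
    Us <- apply(idx, 2L, function(i)
        sum(outer(x[i], x[-i], ">")))
    pl <- mean(Us <= Uobs)
    pg <- mean(Us >= Uobs)
    list(U = Uobs, p = min(1, 2 * min(pl, pg)))
}

# Closed-form normal-equations OLS of response on mass.
oracleOls <- function(mass, response) {
    mx <- mean(mass); my <- mean(response)
    sxx <- sum((mass - mx)^2)
    sxy <- sum((mass - mx) * (response - my))
    syy <- sum((response - my)^2)
    slope <- sxy / sxx
    intercept <- my - slope * mx
    res <- response - intercept - slope * mass
    list(slope = slope, intercept = intercept,
         r2 = sxy^2 / (sxx * syy),
         residualSd = sqrt(sum(res^2) / (length(mass) - 2)))
}

# Small simulated acquisition for IO round-trips and pipeline smoke tests.
smallSim <- function(seed = 11L, nCells = 8L, ...) {
    simulateRun(SimParams(nCells = nCells, nBlanks = 4L,
                          standardMasses = c(0, 173, 3455),
                          standardReplicates = 2L, seed = seed, ...))
}
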