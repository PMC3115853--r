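#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

/* Frontier-synchronous, edge-parallel single-source BFS over the two-array
 * edge representation (head/tail, 1-based, length l = 2m; one slot per
 * direction of every undirected edge).
 *
 * At level t every edge slot is examined: a slot (u, v) with d[u] == t and
 * d[v] still unset settles v at t + 1.  A node's distance is written at most
 * once per level and always with the same value, so slot order cannot change
 * the result -- this is the sequential realization of the one-thread-per-edge
 * kernel.  A second sweep over the slots of the finished level accumulates
 * sigma and raises the per-slot shortest-path flag; sigma[u] is final when
 * read because u settled one level earlier.
 *
 * Distances are doubles with +Inf as the unreachable sentinel; hop counts and
 * path counts are exact in double precision below 2^53.
 */
SEXP C_bfs_edge_parallel(SEXP head_, SEXP tail_, SEXP n_, SEXP source_)
{
    const int *head = INTEGER(head_);
    const int *tail = INTEGER(tail_);
    const R_xlen_t l = XLENGTH(head_);
    const int n = asInteger(n_);
    const int src = asInteger(source_) - 1;

    SEXP d_ = PROTECT(allocVector(REALSXP, n));
    SEXP sigma_ = PROTECT(allocVector(REALSXP, n));
    SEXP pred_ = PROTECT(allocVector(LGLSXP, l));
    double *d = REAL(d_);
    double *sigma = REAL(sigma_);
    int *pred = LOGICAL(pred_);

    for (int i = 0; i < n; i++) {
        d[i] = R_PosInf;
        sigma[i] = 0.0;
    }
    for (R_xlen_t k = 0; k < l; k++) pred[k] = 0;
    d[src] = 0.0;
    sigma[src] = 1.0;

    int levels = 0;
    for (double t = 0.0;; t += 1.0) {
        int updated = 0;
        for (R_xlen_t k = 0; k < l; k++) {
            const int u = head[k] - 1, v = tail[k] - 1;
            if (d[u] == t && d[v] == R_PosInf) {
                d[v] = t + 1.0;
                updated = 1;
            }
        }
        if (!updated) break;
        for (R_xlen_t k = 0; k < l; k++) {
            const int u = head[k] - 1, v = tail[k] - 1;
            if (d[u] == t && d[v] == t + 1.0) {
                sigma[v] += sigma[u];
                pred[k] = 1;
            }
        }
        levels++;
    }

    SEXP out = PROTECT(allocVector(VECSXP, 4));
    SEXP nm = PROTECT(allocVector(STRSXP, 4));
    SET_VECTOR_ELT(out, 0, d_);
    SET_VECTOR_ELT(out, 1, sigma_);
    SET_VECTOR_ELT(out, 2, pred_);
    SET_VECTOR_ELT(out, 3, ScalarInteger(levels));
    SET_STRING_ELT(nm, 0, mkChar("d"));
    SET_STRING_ELT(nm, 1, mkChar("sigma"));
    SET_STRING_ELT(nm, 2, mkChar("pred_flag"));
    SET_STRING_ELT(nm, 3, mkChar("levels"));
    setAttrib(out, R_NamesSymbol, nm);
    UNPROTECT(5);
    return out;
}

/* Brandes-style back-propagation over the shortest-path DAG encoded by the
 * per-slot flags.  Levels are processed in decreasing distance; for each
 * flagged slot (u, v) with d[v] == t:
 *
 *   delta[u]  += sigma[u] / sigma[v] * (1 + delta[v])   (betweenness dependency)
 *   npaths[u] += 1 + npaths[v]                          (geodesic continuations,
 *                                                        used for stress)
 *
 * delta[v] and npaths[v] are final when read because v's own successors all
 * lie one level deeper.  delta[source]/npaths[source] accumulate but carry no
 * meaning and are ignored by consumers.
 */
SEXP C_accumulate_dependencies(SEXP d_, SEXP sigma_, SEXP pred_, SEXP head_,
                               SEXP tail_)
{
    const double *d = REAL(d_);
    const double *sigma = REAL(sigma_);
    const int *pred = LOGICAL(pred_);
    const int *head = INTEGER(head_);
    const int *tail = INTEGER(tail_);
    const R_xlen_t n = XLENGTH(d_);
    const R_xlen_t l = XLENGTH(head_);

    double maxd = 0.0;
    for (R_xlen_t i = 0; i < n; i++)
        if (R_FINITE(d[i]) && d[i] > maxd) maxd = d[i];

    SEXP delta_ = PROTECT(allocVector(REALSXP, n));
    SEXP npaths_ = PROTECT(allocVector(REALSXP, n));
    double *delta = REAL(delta_);
    double *npaths = REAL(npaths_);
    for (R_xlen_t i = 0; i < n; i++) {
        delta[i] = 0.0;
        npaths[i] = 0.0;
    }

    for (double t = maxd; t >= 1.0; t -= 1.0) {
        for (R_xlen_t k = 0; k < l; k++) {
            if (pred[k] && d[tail[k] - 1] == t) {
                const int u = head[k] - 1, v = tail[k] - 1;
                delta[u] += sigma[u] / sigma[v] * (1.0 + delta[v]);
                npaths[u] += 1.0 + npaths[v];
            }
        }
    }

    SEXP out = PROTECT(allocVector(VECSXP, 2));
    SEXP nm = PROTECT(allocVector(STRSXP, 2));
    SET_VECTOR_ELT(out, 0, delta_);
    SET_VECTOR_ELT(out, 1, npaths_);
    SET_STRING_ELT(nm, 0, mkChar("delta"));
    SET_STRING_ELT(nm, 1, mkChar("npaths"));
    setAttrib(out, R_NamesSymbol, nm);
    UNPROTECT(4);
    return out;
}

static const R_CallMethodDef CallEntries[] = {
    {"C_bfs_edge_parallel", (DL_FUNC) &C_bfs_edge_parallel, 4},
    {"C_accumulate_dependencies", (DL_FUNC) &C_accumulate_dependencies, 5},
    {NULL, NULL, 0}
};

void R_init_netcentral(DllInfo *dll)
{
    R_registerRoutines(dll, NULL, CallEntries, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
}
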