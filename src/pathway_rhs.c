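/* Compiled right-hand side for the signaling pathway ODE system.
 *
 * The model context (topology, parameter indices, parameter values) is
 * loaded into static storage with set_pathway_ctx() before each
 * integration; deSolve then calls pathway_deriv() directly, avoiding any
 * per-step R evaluation.  States are active fractions; the conservation
 * law (active + inactive = total = 1) is structural: only the active
 * fraction is integrated and the inactive fraction enters the rate laws
 * as 1 - a.
 */
#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

#define MAX_NODES 64
#define MAX_EDGES 256
#define MAX_PARS  1024

static int nn = 0, ne = 0;

/* per node: clamped flag and parameter indices (-1 = absent), 0-based */
static int nd_clamped[MAX_NODES], nd_stim[MAX_NODES], nd_kact[MAX_NODES],
           nd_kdec[MAX_NODES], nd_level[MAX_NODES];

/* per edge: endpoints, sign (+1 activating / -1 inhibiting), law
 * (1 = Michaelis-Menten, 0 = mass action), k and K parameter indices */
static int ed_src[MAX_EDGES], ed_tgt[MAX_EDGES], ed_sign[MAX_EDGES],
           ed_mm[MAX_EDGES], ed_k[MAX_EDGES], ed_K[MAX_EDGES];

static double par[MAX_PARS];

SEXP set_pathway_ctx(SEXP node_info, SEXP edge_info, SEXP params)
{
    int i, np;
    int *ni, *ei;
    double *pv;

    if (!isInteger(node_info) || !isInteger(edge_info) || !isReal(params))
        error("invalid pathway context types");

    nn = ncols(node_info);
    ne = ncols(edge_info);
    np = length(params);
    if (nrows(node_info) != 5) error("node_info must have 5 rows");
    if (nrows(edge_info) != 6) error("edge_info must have 6 rows");
    if (nn < 1 || nn > MAX_NODES) error("node count out of range");
    if (ne > MAX_EDGES) error("edge count out of range");
    if (np < 1 || np > MAX_PARS) error("parameter count out of range");

    ni = INTEGER(node_info);
    for (i = 0; i < nn; i++) {
        nd_clamped[i] = ni[5 * i + 0];
        nd_stim[i]    = ni[5 * i + 1];
        nd_kact[i]    = ni[5 * i + 2];
        nd_kdec[i]    = ni[5 * i + 3];
        nd_level[i]   = ni[5 * i + 4];
    }
    ei = INTEGER(edge_info);
    for (i = 0; i < ne; i++) {
        ed_src[i]  = ei[6 * i + 0];
        ed_tgt[i]  = ei[6 * i + 1];
        ed_sign[i] = ei[6 * i + 2];
        ed_mm[i]   = ei[6 * i + 3];
        ed_k[i]    = ei[6 * i + 4];
        ed_K[i]    = ei[6 * i + 5];
        if (ed_src[i] < 0 || ed_src[i] >= nn || ed_tgt[i] < 0 || ed_tgt[i] >= nn)
            error("edge endpoint out of range");
    }
    pv = REAL(params);
    for (i = 0; i < np; i++) par[i] = pv[i];

    return ScalarInteger(nn);
}

void pathway_deriv(int *neq, double *t, double *y, double *ydot,
                   double *yout, int *ip)
{
    int i, j;
    double act[MAX_NODES];

    if (*neq != nn) error("state length does not match pathway context");

    for (i = 0; i < nn; i++) {
        double a = nd_clamped[i] ? par[nd_level[i]] : y[i];
        if (a < 0.0) a = 0.0;
        if (a > 1.0) a = 1.0;
        act[i] = a;
    }

    for (i = 0; i < nn; i++) {
        double d = 0.0, a, inact;
        if (nd_clamped[i]) { ydot[i] = 0.0; continue; }
        a = act[i];
        inact = 1.0 - a;
        if (nd_stim[i] >= 0) d += par[nd_stim[i]] * inact;
        if (nd_kact[i] >= 0) d += par[nd_kact[i]] * inact;
        if (nd_kdec[i] >= 0) d -= par[nd_kdec[i]] * a;
        ydot[i] = d;
    }

    for (j = 0; j < ne; j++) {
        int tg = ed_tgt[j];
        double s, v, sub;
        if (nd_clamped[tg]) continue;
        s = act[ed_src[j]];
        if (s <= 0.0) continue;
        if (ed_sign[j] > 0) {            /* activation converts inactive form */
            sub = 1.0 - act[tg];
            v = ed_mm[j] ? par[ed_k[j]] * s * sub / (par[ed_K[j]] + sub)
                         : par[ed_k[j]] * s * sub;
            ydot[tg] += v;
        } else {                         /* inhibition converts active form */
            sub = act[tg];
            v = ed_mm[j] ? par[ed_k[j]] * s * sub / (par[ed_K[j]] + sub)
                         : par[ed_k[j]] * s * sub;
            ydot[tg] -= v;
        }
    }
}

static const R_CallMethodDef call_entries[] = {
    {"set_pathway_ctx", (DL_FUNC) &set_pathway_ctx, 3},
    {NULL, NULL, 0}
};

/* registered so deSolve can resolve the derivative symbol by name */
static const R_CMethodDef c_entries[] = {
    {"pathway_deriv", (DL_FUNC) &pathway_deriv, 6},
    {NULL, NULL, 0}
};

void R_init_pathwayCRA(DllInfo *dll)
{
    R_registerRoutines(dll, c_entries, call_entries, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
}
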