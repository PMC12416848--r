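/* Generalized Lotka-Volterra right-hand side and analytic Jacobian for
 * communities with competition, consumer-resource and mutualistic links under
 * Type II functional responses.  Called by deSolve's lsoda via dllname lookup;
 * parameters are staged beforehand with glv_stage() because the system size
 * changes between integration windows (extinctions shrink the state).
 *
 * Per-capita growth of species i:
 *   g_i = r_i - delta*n+_i - s_i x_i - sum_j c_ij x_j
 *         - sum_j pm_ij x_j / (1 + hp * sum_k pp_jk x_k)     (loss to consumers,
 *                                                             saturated by the
 *                                                             consumer's intake)
 *         + A_i / (1 + hp*A_i) + M_i / (1 + hm*M_i),
 * with A_i = sum_k pp_ik x_k (consumer intake), M_i = sum_k m_ik x_k
 * (mutualistic intake), n+_i the number of links where i is consumer or
 * mutualist.  dx_i/dt = x_i * g_i.
 */

#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>
#include <stdlib.h>
#include <string.h>

static int    S = 0;
static double par_delta = 0.0, par_hp = 0.0, par_hm = 0.0;
static double *rv = NULL, *sv = NULL, *nplus = NULL;
static double *cm = NULL, *pp = NULL, *pm = NULL, *mm = NULL;
static double *wk = NULL;   /* workspace, 6*S doubles */

static void glv_free_all(void)
{
    free(rv); free(sv); free(nplus);
    free(cm); free(pp); free(pm); free(mm); free(wk);
    rv = sv = nplus = cm = pp = pm = mm = wk = NULL;
    S = 0;
}

static double *copy_vec(SEXP x, R_xlen_t n)
{
    double *out = (double *) malloc(sizeof(double) * (size_t) n);
    if (out == NULL) error("ecoassembly: allocation failure (%lld doubles)",
                           (long long) n);
    memcpy(out, REAL(x), sizeof(double) * (size_t) n);
    return out;
}

/* Stage the community for subsequent derivs/jac calls.
 * r, s, nplus: length S; c, pplus, pminus, m: S x S column-major. */
SEXP glv_stage(SEXP n_, SEXP delta_, SEXP hp_, SEXP hm_,
               SEXP r_, SEXP s_, SEXP nplus_,
               SEXP c_, SEXP pp_, SEXP pm_, SEXP m_)
{
    int n = INTEGER(n_)[0];
    if (n < 1) error("ecoassembly: empty community staged");
    R_xlen_t n2 = (R_xlen_t) n * n;
    if (XLENGTH(r_) != n || XLENGTH(s_) != n || XLENGTH(nplus_) != n ||
        XLENGTH(c_) != n2 || XLENGTH(pp_) != n2 ||
        XLENGTH(pm_) != n2 || XLENGTH(m_) != n2)
        error("ecoassembly: staged dimensions are inconsistent");

    glv_free_all();
    S = n;
    par_delta = REAL(delta_)[0];
    par_hp    = REAL(hp_)[0];
    par_hm    = REAL(hm_)[0];
    rv    = copy_vec(r_, n);
    sv    = copy_vec(s_, n);
    nplus = copy_vec(nplus_, n);
    cm    = copy_vec(c_, n2);
    pp    = copy_vec(pp_, n2);
    pm    = copy_vec(pm_, n2);
    mm    = copy_vec(m_, n2);
    wk = (double *) malloc(sizeof(double) * (size_t) (6 * n));
    if (wk == NULL) error("ecoassembly: allocation failure (workspace)");
    return R_NilValue;
}

/* shared pre-computation: A, Dp, M, Dm, u = y/Dp, g */
static void glv_core(const double *y, double *A, double *Dp,
                     double *M, double *Dm, double *u, double *g)
{
    int i, j;
    for (i = 0; i < S; i++) { A[i] = 0.0; M[i] = 0.0; }
    for (j = 0; j < S; j++) {
        double yj = y[j];
        if (yj == 0.0) continue;
        const double *ppj = pp + (size_t) S * j;
        const double *mmj = mm + (size_t) S * j;
        for (i = 0; i < S; i++) {
            A[i] += ppj[i] * yj;
            M[i] += mmj[i] * yj;
        }
    }
    for (i = 0; i < S; i++) {
        Dp[i] = 1.0 + par_hp * A[i];
        Dm[i] = 1.0 + par_hm * M[i];
        u[i]  = y[i] / Dp[i];
    }
    for (i = 0; i < S; i++)
        g[i] = rv[i] - par_delta * nplus[i] - sv[i] * y[i]
             + A[i] / Dp[i] + M[i] / Dm[i];
    for (j = 0; j < S; j++) {
        double yj = y[j], uj = u[j];
        if (yj == 0.0 && uj == 0.0) continue;
        const double *cmj = cm + (size_t) S * j;
        const double *pmj = pm + (size_t) S * j;
        for (i = 0; i < S; i++)
            g[i] -= cmj[i] * yj + pmj[i] * uj;
    }
}

void glv_derivs(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip)
{
    if (*neq != S) error("ecoassembly: derivs called before staging");
    double *A = wk, *Dp = wk + S, *M = wk + 2 * S,
           *Dm = wk + 3 * S, *u = wk + 4 * S, *g = wk + 5 * S;
    glv_core(y, A, Dp, M, Dm, u, g);
    for (int i = 0; i < S; i++) ydot[i] = y[i] * g[i];
}

/* Full analytic Jacobian: J_ij = d(x_i g_i)/dx_j = delta_ij g_i + x_i dg_i/dx_j
 * dg_i/dx_j = -s_i delta_ij - c_ij - pm_ij/Dp_j
 *             + sum_l pm_il x_l hp pp_lj / Dp_l^2     (consumer j relieves l's
 *                                                      pressure by saturating)
 *             + pp_ij/Dp_i^2 + m_ij/Dm_i^2
 */
void glv_jac(int *neq, double *t, double *y, int *ml, int *mu,
             double *pd, int *nrowpd, double *yout, int *ip)
{
    if (*neq != S) error("ecoassembly: jac called before staging");
    int n = S, nr = *nrowpd, i, j, l;
    double *A = wk, *Dp = wk + n, *M = wk + 2 * n,
           *Dm = wk + 3 * n, *u = wk + 4 * n, *g = wk + 5 * n;
    glv_core(y, A, Dp, M, Dm, u, g);

    double *v    = (double *) R_alloc((size_t) n, sizeof(double));
    double *ip2  = (double *) R_alloc((size_t) n, sizeof(double));
    double *im2  = (double *) R_alloc((size_t) n, sizeof(double));
    for (l = 0; l < n; l++) {
        v[l]   = y[l] * par_hp / (Dp[l] * Dp[l]);
        ip2[l] = 1.0 / (Dp[l] * Dp[l]);
        im2[l] = 1.0 / (Dm[l] * Dm[l]);
    }

    for (j = 0; j < n; j++) {
        const double *cmj = cm + (size_t) n * j;
        const double *pmj = pm + (size_t) n * j;
        const double *ppj = pp + (size_t) n * j;
        const double *mmj = mm + (size_t) n * j;
        double *col = pd + (size_t) nr * j;
        for (i = 0; i < n; i++) {
            double w = 0.0;
            /* sum_l pm_il v_l pp_lj */
            const double *pmi = pm + i;             /* stride n over l */
            for (l = 0; l < n; l++) {
                double plj = pp[l + (size_t) n * j];
                if (plj != 0.0) w += pmi[(size_t) n * l] * v[l] * plj;
            }
            double dg = -cmj[i] - pmj[i] / Dp[j] + w
                      + ppj[i] * ip2[i] + mmj[i] * im2[i];
            if (i == j) dg -= sv[i];
            col[i] = y[i] * dg + (i == j ? g[i] : 0.0);
        }
    }
}

static const R_CallMethodDef callMethods[] = {
    {"glv_stage", (DL_FUNC) &glv_stage, 11},
    {NULL, NULL, 0}
};

void R_init_ecoassembly(DllInfo *dll)
{
    static const R_CMethodDef cMethods[] = {
        {"glv_derivs", (DL_FUNC) &glv_derivs, 6},
        {"glv_jac",    (DL_FUNC) &glv_jac,    9},
        {NULL, NULL, 0}
    };
    R_registerRoutines(dll, cMethods, callMethods, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
}

void R_unload_ecoassembly(DllInfo *dll)
{
    glv_free_all();
}
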