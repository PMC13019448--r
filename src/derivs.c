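/* Compiled right-hand side of the generalized S-system ODE,
 *   dx/dt = S r(x, xs) + u,
 * with power-law rates r_k = alpha_k prod_j X_j^G[j,k].
 *
 * The model is passed once through c_bst_set_model() as a flat double
 * vector (layout below); deSolve then calls c_bst_derivs() without any
 * per-call parameter marshalling. The input u is constant within an
 * integration segment (the R driver restarts integration at pulse edges).
 *
 * layout: [n, m, p, eps, S (n*p, column-major), G ((n+m)*p, column-major),
 *          alpha (p), xs (m), u (n)]
 */
#include <R.h>
#include <Rinternals.h>
#include <math.h>
#include <stdlib.h>
#include <string.h>

static double *bst_par = NULL;
static R_xlen_t bst_par_len = 0;

SEXP c_bst_set_model(SEXP par)
{
    R_xlen_t len = XLENGTH(par);
    double *buf = (double *) realloc(bst_par, (size_t) len * sizeof(double));
    if (buf == NULL)
        error("bstkit: failed to allocate model parameter buffer");
    bst_par = buf;
    memcpy(bst_par, REAL(par), (size_t) len * sizeof(double));
    bst_par_len = len;
    return R_NilValue;
}

void c_bst_derivs(int *neq, double *t, double *y, double *ydot,
                  double *yout, int *ip)
{
    if (bst_par == NULL)
        error("bstkit: model parameters not set before derivative call");
    const int n = (int) bst_par[0];
    const int m = (int) bst_par[1];
    const int p = (int) bst_par[2];
    const double eps = bst_par[3];
    const double *S = bst_par + 4;
    const double *G = S + (size_t) n * p;
    const double *alpha = G + (size_t) (n + m) * p;
    const double *xs = alpha + p;
    const double *u = xs + m;

    for (int i = 0; i < n; i++)
        ydot[i] = u[i];
    for (int k = 0; k < p; k++) {
        double rk = alpha[k];
        if (rk == 0.0)
            continue;
        const double *gk = G + (size_t) k * (n + m);
        for (int j = 0; j < n + m; j++) {
            const double g = gk[j];
            if (g != 0.0) {  /* zero order contributes exactly 1, even at X = 0 */
                double xj = (j < n) ? y[j] : xs[j - n];
                if (xj < eps)
                    xj = eps;
                rk *= pow(xj, g);
            }
        }
        const double *sk = S + (size_t) k * n;
        for (int i = 0; i < n; i++)
            if (sk[i] != 0.0)
                ydot[i] += sk[i] * rk;
    }
}
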