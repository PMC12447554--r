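/* Right-hand side of the two-step strand-exchange model, compiled for deSolve.
 *
 * Species order: y[0]=input, y[1]=probe, y[2]=t_only, y[3]=F, y[4]=Q (molar).
 * Parameters:    kon (M^-1 s^-1), koff (s^-1), kbm (s^-1).
 */
#include <R.h>

static double parms[3];
#define kon  parms[0]
#define koff parms[1]
#define kbm  parms[2]

void fourway_initmod(void (*odeparms)(int *, double *))
{
    int n = 3;
    odeparms(&n, parms);
}

void fourway_derivs(int *neq, double *t, double *y, double *ydot,
                    double *yout, int *ip)
{
    double bind    = kon * y[0] * y[1];
    double unbind  = koff * y[2];
    double resolve = kbm * y[2];

    ydot[0] = unbind - bind;           /* d[input]/dt  */
    ydot[1] = unbind - bind;           /* d[probe]/dt  */
    ydot[2] = bind - unbind - resolve; /* d[t_only]/dt */
    ydot[3] = resolve;                 /* d[F]/dt      */
    ydot[4] = resolve;                 /* d[Q]/dt      */
}

/* Batched variant: neq/5 independent replicas of the five-species system
 * sharing one parameter set but differing in initial conditions, so a
 * whole concentration panel integrates in a single solver call. */
void fourway_derivs_multi(int *neq, double *t, double *y, double *ydot,
                          double *yout, int *ip)
{
    int nb = *neq / 5;
    for (int b = 0; b < nb; b++) {
        double *yb = y + 5 * b;
        double *db = ydot + 5 * b;
        double bind    = kon * yb[0] * yb[1];
        double unbind  = koff * yb[2];
        double resolve = kbm * yb[2];
        db[0] = unbind - bind;
        db[1] = unbind - bind;
        db[2] = bind - unbind - resolve;
        db[3] = resolve;
        db[4] = resolve;
    }
}

void fourway_jac_multi(int *neq, double *t, double *y, int *ml, int *mu,
                       double *pd, int *nrowpd, double *yout, int *ip)
{
    int n = *nrowpd;
    int nb = *neq / 5;
    for (int j = 0; j < *neq; j++)
        for (int i = 0; i < *neq; i++)
            pd[j * n + i] = 0.0;
    for (int b = 0; b < nb; b++) {
        int o = 5 * b;
        double a = kon * y[o + 1];
        double c = kon * y[o];
        pd[(o + 0) * n + o + 0] = -a;  pd[(o + 1) * n + o + 0] = -c;
        pd[(o + 2) * n + o + 0] = koff;
        pd[(o + 0) * n + o + 1] = -a;  pd[(o + 1) * n + o + 1] = -c;
        pd[(o + 2) * n + o + 1] = koff;
        pd[(o + 0) * n + o + 2] =  a;  pd[(o + 1) * n + o + 2] =  c;
        pd[(o + 2) * n + o + 2] = -(koff + kbm);
        pd[(o + 2) * n + o + 3] = kbm;
        pd[(o + 2) * n + o + 4] = kbm;
    }
}

/* Full analytic Jacobian (column-major in pd, nrowpd rows per column). */
void fourway_jac(int *neq, double *t, double *y, int *ml, int *mu,
                 double *pd, int *nrowpd, double *yout, int *ip)
{
    int n = *nrowpd;
    for (int j = 0; j < *neq; j++)
        for (int i = 0; i < *neq; i++)
            pd[j * n + i] = 0.0;

    double a = kon * y[1];  /* d(bind)/d[input] */
    double b = kon * y[0];  /* d(bind)/d[probe] */

    pd[0 * n + 0] = -a;  pd[1 * n + 0] = -b;  pd[2 * n + 0] = koff;
    pd[0 * n + 1] = -a;  pd[1 * n + 1] = -b;  pd[2 * n + 1] = koff;
    pd[0 * n + 2] =  a;  pd[1 * n + 2] =  b;  pd[2 * n + 2] = -(koff + kbm);
    pd[2 * n + 3] = kbm;
    pd[2 * n + 4] = kbm;
}
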